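(((((T1:0.1299542498,T2:0.798538022):0.1054388199,((T3:0.5284959297,T4:0.05480886321):0.6752741714,T5:0.8342888169):0.2199859719):0.1642893483,((T6:0.6054135987,T7:0.9595648486):0.795618874,((T8:0.8451105377,(T9:0.2033142503,T10:0.1599907828):0.1980735129):0.2440943464,(T11:0.7474981484,T12:0.5024173723):0.6071735388):0.2826970317):0.46851094):0.03968625306,((T13:0.2510552653,(T14:0.5134946916,(T15:0.289185018,((T16:0.8701978561,T17:0.7233874134):0.5233471799,T18:0.4366767153):0.03206478897):0.480602192):0.218331214):0.118970474,(T19:0.792550477,((T20:0.3144374762,((T21:0.6761733925,T22:0.1777396901):0.3838016295,T23:0.517273891):0.09134512581):0.6046297159,((T24:0.5172844203,T25:0.1250647746):0.7718326629,(((T26:0.4126863056,T27:0.8937390461):0.2387076928,(((T28:0.4114615445,T29:0.7320631915):0.9749002059,(T30:0.3644387254,T31:0.2617366672):0.8443081507):0.3579018542,T32:0.7767105615):0.2706922067):0.3486515917,(T33:0.5574470195,(T34:0.05650029122,T35:0.9852950184):0.9673052623):0.7891828059):0.001849327935):0.1205770087):0.772255759):0.005172016798):0.8144775752):0.1217055283,(((((((T36:0.4240756268,T37:0.6627168886):0.5320494359,(T38:0.320437351,T39:0.7745184337):0.7011033338):0.0281185708,((T40:0.8811289761,T41:0.1050626759):0.5843752096,T42:0.7998392712):0.4687810936):0.98371508,(((T43:0.5305589696,T44:0.4185260748):0.1582721476,T45:0.1401433498):0.3774518997,((T46:0.3132757884,T47:0.5105491416):0.9046456115,(T48:0.1679382762,(T49:0.2326836148,T50:0.04857526254):0.9951177775):0.3281787275):0.4489364095):0.684553131):0.1195435075,T51:0.0213484033):0.526800344,((T52:0.6837767416,T53:0.6836684488):0.7885611216,((T54:0.8711586804,T55:0.979231867):0.3926494499,(T56:0.2004129407,T57:0.8335399218):0.2087574357):0.8305711057):0.2549476316):0.7986427285,(((T58:0.2201754388,T59:0.2885390725):0.4021279651,T60:0.9803420033):0.1977375206,(T61:0.08817608724,T62:0.464010678):0.4826433936):0.9675286051):0.85759626);
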