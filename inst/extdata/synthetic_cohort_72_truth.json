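{"r":[1.1626852897838,-0.585924465893051,1.78546500331661,-1.33259371048501,-0.446566766553219,0.569606122374976,-2.88971761441412,-0.869018343326555,-0.461702683149641,-0.555540910137444,-0.0201353678515895,-0.150382224136063,-0.628126755843964,1.32322085193283,-1.52135057001199,-0.437427868856691,0.970577579543399,0.0282226444247749,-0.0857821886527593,0.389214404984942,0.236687367712904,-0.144440226694072,0.722229700806146,0.369906857410192,-0.242066314481781,-1.47206331842053,-0.596159545765696,-1.1467001312186,-2.47463643305885,-0.613508578410268,-0.216311514038102,1.5901457684867,1.55614327565194,1.10845089348356,-1.09734184488477,-1.86060571637755,-0.913578847977252,1.24556891198713,0.0878547183607045,0.423481895050245,-0.818483016568666,-1.54256783707378,0.555882145731614,-0.369028970506554,-1.04733828003612,0.0181799162475183,0.881877505756162,0.881861495242933,1.02624318512833,-0.381309179346182,1.09943523714178,-0.0309171311816436,0.190339419951192,1.33520653499813,0.730552334545457,0.0562018971641194,1.32930562968532,-0.408119942611893,-0.818257106699263,0.358945669924477,0.058716060046925,-0.0694365882443973,-0.38481626773716,-0.874323457442456,1.19633066850945,-1.66119954697052,1.16521207827703,-1.0696619776497,0.908883540128663,-1.31750742099905,0.655429955993348,-0.66037182391874],"planted":["planted_01","planted_02","planted_03"],"noise":["noise_01","noise_02","noise_03"],"rho":0.8,"objectiveEffects":[4,1.5,1.5],"seed":20}
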