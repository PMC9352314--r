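true,Faltlbach,Holzhuettenboden,Taglesbach,Kothbergbach,Bodingbach,Seebach,Lunz (Ybbs),Grossau (Ybbs),Goestling (Ybbs)
Faltlbach,17,2,0,2,2,0,0,0,0
Holzhuettenboden,1,4,6,0,7,0,2,6,0
Taglesbach,0,8,1,1,9,0,0,0,0
Kothbergbach,10,0,1,9,2,0,0,0,0
Bodingbach,1,0,3,1,11,0,3,1,0
Seebach,0,6,0,0,1,10,0,1,1
Lunz (Ybbs),0,7,1,1,6,0,6,1,0
Grossau (Ybbs),0,3,0,1,3,0,7,2,0
Goestling (Ybbs),0,2,4,0,2,1,4,3,2
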