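scientific_name,common_name,n_observations,fraction_heard,in_aru
Phylloscopus umbrovirens,brown woodland warbler,50,0.94,TRUE
Bradypterus cinnamomeus,cinnamon bracken warbler,38,0.95,TRUE
Apalis porphyrolaema,chestnut-throated apalis,34,0.97,TRUE
Zosterops poliogastrus,montane white-eye,25,0.84,TRUE
Pogonocichla stellata,white-starred robin,21,0.86,TRUE
Poicephalus gulielmi,red-fronted parrot,15,0.60,TRUE
Tauraco hartlaubi,Hartlaub's turaco,13,0.92,TRUE
Chloropeta similis,mountain yellow warbler,11,0.91,TRUE
Cyanomitra olivacea,olive sunbird,8,0.50,TRUE
Stephanoaetus coronatus,crowned eagle,6,1.00,TRUE
Parus albiventris,white-bellied tit,4,0.75,FALSE
Muscicapa adusta,African dusky flycatcher,3,1.00,TRUE
Pseudoalcippe abyssinica,African hill babbler,3,0.67,FALSE
Pheoniculus bollei,white-headed wood-hoopoe,3,0.67,TRUE
Andropadus nigriceps,mountain greenbul,3,0.67,TRUE
Cinnyris venustus,variable sunbird,1,1.00,FALSE
Coracina caesia,grey cuckooshrike,1,1.00,FALSE
Accipiter tachiro,African goshawk,1,1.00,TRUE
Apalis cinerea,grey apalis,1,1.00,TRUE
Cinnyris mediocris,eastern double-collared sunbird,1,1.00,TRUE
Pycnonotus barbatus,common bulbul,1,1.00,TRUE
Batis molitor,chin-spot batis,1,1.00,FALSE
Serinus flavivertex,yellow-crowned canary,1,1.00,FALSE
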