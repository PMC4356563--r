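"electrode_name","contact_number","x_mm","y_mm","z_mm","label"
"A",1,-32,12,-12,"ictal"
"A",2,-35.8401228858986,12.9600307214746,-12.5760184328848,"ictal"
"A",3,-39.6802457717971,13.9200614429493,-13.1520368657696,"ictal"
"A",4,-43.5203686576957,14.8800921644239,-13.7280552986544,"interictal"
"A",5,-47.3604915435942,15.8401228858986,-14.3040737315391,"interictal"
"HA",1,-32,4,-18,"ictal"
"HA",2,-35.8401228858986,4.96003072147464,-18.5760184328848,"ictal"
"HA",3,-39.6802457717971,5.92006144294928,-19.1520368657696,"ictal"
"HA",4,-43.5203686576957,6.88009216442392,-19.7280552986544,"ictal"
"HA",5,-47.3604915435942,7.84012288589855,-20.3040737315391,"ictal"
"HA",6,-51.2006144294928,8.80015360737319,-20.8800921644239,"interictal"
"HA",7,-55.0407373153913,9.76018432884783,-21.4561105973087,"interictal"
"HA",8,-58.8808602012899,10.7202150503225,-22.0321290301935,"interictal"
"HA",9,-62.7209830871884,11.6802457717971,-22.6081474630783,"interictal"
"HA",10,-66.561105973087,12.6402764932717,-23.184165895963,"interictal"
"HP",1,-30,-8,-20,"interictal"
"HP",2,-33.8401228858986,-7.03996927852536,-20.5760184328848,"interictal"
"HP",3,-37.6802457717971,-6.07993855705072,-21.1520368657696,"interictal"
"HP",4,-41.5203686576957,-5.11990783557608,-21.7280552986544,"interictal"
"TA",1,-58,34,-16,"interictal"
"TA",2,-61.713906763541,35.4855627054164,-16,"interictal"
"TA",3,-65.4278135270821,36.9711254108328,-16,"interictal"
"E",1,-48,18,-22,"interictal"
"E",2,-51.8401228858986,18.9600307214746,-22.5760184328848,"interictal"
"F",1,-30,52,10,"inactive"
"F",2,-33.3218191941496,53.9930915164898,10.9965457582449,"inactive"
"F",3,-36.6436383882992,55.9861830329795,11.9930915164898,"inactive"
"F",4,-39.9654575824488,57.9792745494693,12.9896372747346,"inactive"
"F",5,-43.2872767765984,59.972366065959,13.9861830329795,"inactive"
"P",1,-34,-40,18,"inactive"
"P",2,-37.481553119114,-41.3926212476456,19.3926212476456,"inactive"
"P",3,-40.9631062382279,-42.7852424952912,20.7852424952912,"inactive"
"P",4,-44.4446593573419,-44.1778637429368,22.1778637429368,"inactive"
"P",5,-47.9262124764558,-45.5704849905823,23.5704849905823,"inactive"
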