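(Crocodylus:250,(Marasuchus:8,(Lesothosaurus:36,(Plateosaurus:19,(Coelophysis:15,(Dilophosaurus:15,(Allosaurus:41,(Tyrannosaurus:98,((Velociraptor:43,Deinonychus:3)Dromaeosauridae:45,(Archaeopteryx:5,(Gallus:30,Phasianus:30)Phasianidae:125)Avialae:5)Eumaniraptora:5)Coelurosauria:26)Avetheropoda:10)Averostra:24)Neotheropoda:8)Saurischia:2)Dinosauria:10)Dinosauromorpha:5)Archosauria;
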