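case_id,SCHOOLS,SBI,MC,SM,CCY,HI_UPTAKE
Blekinge,1,0,1,0,0,1
Dalarna,1,0,1,0,0,1
Gavleborg,1,0,1,0,0,1
Gotland,2,0,0,0,0,1
Halland,2,0,1,0,0,1
Jamtland,2,1,0,0,0,1
Jonkoping,2,0,0,1,1,1
Skane,1,0,1,0,1,0
Kalmar,1,0,0,0,1,0
Kronoberg,1,1,0,1,0,0
Norrbotten,1,0,0,0,0,0
Orebro,0,0,1,0,0,0
Ostergotland,0,1,1,0,1,0
Sodermanland,0,0,0,1,1,0
Stockholm,0,1,0,0,1,0
Uppsala,0,0,0,0,1,0
Varmland,0,0,1,1,0,0
Vasterbotten,0,1,0,1,0,0
Vasternorrland,0,0,0,0,0,0
Vastmanland,0,1,1,1,1,0
Vastra_Gotaland,0,0,0,0,0,0
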