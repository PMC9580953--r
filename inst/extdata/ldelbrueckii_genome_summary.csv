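strain,accession,size_mb,gc_percent,cds,source
LJJ,NZ_CP049052.1,1.89,49.50,1604,Dairy products
KLDS1.0207,NZ_CP032451.1,1.87,49.80,1607,Dairy products
DSM 20080,NZ_CP019120.1,1.87,49.80,1680,Environment
2038,NC_017469.1,1.87,49.70,1792,
ATCC 11842,NC_008054.1,1.86,49.70,1683,Bulgarian Yogurt
TUA4408L,NZ_CP021136.1,2.01,49.90,1801,Sunki-zuke
DSM20074,NZ_CP018615.1,1.95,49.60,1721,Environment
CNRZ327,GCF_000751695.1,2.11,49.60,1525,Cheese
CIDCA 133,CP065513,2.13,49.59,1921,Raw cow's milk
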