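"id","smiles","activity_pct"
"dmt","CN(C)CCc1c[nH]c2ccccc12",39.753030781869
"fluoroindole","Fc1ccc2[nH]ccc2c1",43.5366763783756
"indole_carbinol","OCc1c[nH]c2ccccc12",47.0197759469604
"benzamide","NC(=O)c1ccccc1",41.7613883948092
"phenol","Oc1ccccc1",34.5546395652058
"tryptophan","NC(Cc1c[nH]c2ccccc12)C(=O)O",65.4039989635957
"indole_aldehyde","O=Cc1c[nH]c2ccccc12",37.5634494001598
"dimethylindole","Cc1[nH]c2ccccc2c1C",29.1450318380523
"ethanolamine","NCCO",62.204784412338
"hydroxyindole","Oc1ccc2[nH]ccc2c1",50.7040680150106
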