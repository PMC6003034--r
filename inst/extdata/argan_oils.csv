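sample_id,region,extraction,palmitic,stearic,oleic,linoleic
TUN-SOL,Tunisia,solvent,"16,13","7,10","52,53","24,24"
MAR-CP-COSM,Morocco,cold pressing,"14,43","6,17","47,17","32,22"
MAR-SOL,Morocco,solvent,"12,79","5,35","45,53","34,64"
MAR-CP-ED,Morocco,cold pressing,"13,5","5,5",47,33
ALG-TIN-SOL,Algeria-Tindouf,solvent,"13, 84","5, 68","50,30","28, 99"
ALG-TIN-CP,Algeria-Tindouf,cold pressing,13,"5,2","44,3","35,8"
ALG-MOS-SOL,Algeria-Mostaganem,solvent,"12, 28","4, 72","45,02","36, 80"
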