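{"name":"bloodAging","composition":{"baselineLogits":{"Bas":-4.32667653959072,"Eos":-4.32667653959072,"Neu":-1.13451657711832,"Mono":-2.50959926237837,"Bnv":-2.08496340728193,"Bmem":-5.25256856743699,"CD4nv":-1.92133398350013,"CD4mem":-3.6149597780362,"Treg":-4.32667653959072,"CD8nv":-3.32667653959072,"CD8mem":-3.52217804458523,"NK":-3.06298450056316},"ageSlopes":[0,0,0.03,0,-0.02,0.02,-0.02,0.02,0,-0.02,0.02,0],"ageKnots":[999,999,18,999,999,999,999,999,999,999,999,999],"diseaseShifts":[0,0,0.45,-0.15,-0.4,-0.4,-0.3,-0.25,0.5,-0.4,-0.5,-0.15],"dispersion":0.7,"axisLoadings":[0,0,0,0,-1,1,-1,1,0,-1,1,0],"axisSd":0.8,"newbornOverrides":[]},"nCpgsPerType":12,"refDelta":0.35,"nDriftCpgs":20,"driftSlope":0.0003,"intrinsicSd":7,"noisePrecision":100,"n":2000,"diseasePrev":0,"newbornFrac":0.1,"diseaseDriftYears":0}
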