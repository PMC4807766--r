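center,model,sres,dTavg,dPrec,dPrat
CCCMA,CGCM3.1 (T47),A2,5,18.2,-4.2
CCCMA,CGCM3.1 (T47),A1B,3.9,15.3,-3.6
CCCMA,CGCM3.1 (T47),B1,2.8,7.7,-3.2
CNRM,CM3,A2,4.5,9.4,-4
CNRM,CM3,A1B,3.5,8.4,-3.1
CNRM,CM3,B1,2.2,5.4,-2.5
CSIRO,MK3.0,A2,3.9,11.8,-1.6
CSIRO,MK3.0,A1B,2.8,6.7,-2.8
CSIRO,MK3.0,B1,1.8,4.8,-1.5
CSIRO,MK3.5,A2,4.7,11,-2.7
CSIRO,MK3.5,A1B,3.9,15.4,-0.7
CSIRO,MK3.5,B1,2.9,7.3,-2.5
GFDL,CM2.0,A2,5.2,3.9,-7.4
GFDL,CM2.0,A1B,4.3,9.6,-3.4
GFDL,CM2.0,B1,2.8,8.1,-2
IPSL,CM4,A2,6.9,2.8,-2.4
IPSL,CM4,A1B,5.8,5.4,-2.8
IPSL,CM4,B1,4.2,1.6,-2.2
CCSR,MIROC3.2 (Medres),A2,6.8,-0.8,-9.3
CCSR,MIROC3.2 (Medres),A1B,5.8,3.1,-7.1
CCSR,MIROC3.2 (Medres),B1,4,5.7,-5.2
MIUB,ECHO-G,A2,5,12.6,-0.1
MIUB,ECHO-G,A1B,4.8,11.4,-0.2
MIUB,ECHO-G,B1,3.4,5.9,0.3
MRI,CGCM2.3.2,A2,3.7,13.7,-1.1
MRI,CGCM2.3.2,A1B,3.3,11,-1.3
MRI,CGCM2.3.2,B1,2.5,8.9,0.2
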