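population,Latitude,Mig.D,Mig.S,CAMax,CAMin,CARange,CRMax,CRCMax,CRAve,HAMax,HAMin,HARange,HRMax,HRCMax,HRAve
Coleman,40.398,441,0.279,19.5,8.0,11.5,13.5,12.0,10.0,16.0,5.5,10.5,10.5,9.0,8.0
Elk River,42.740,22,1.591,16.0,7.5,8.5,11.0,10.0,9.0,14.5,6.0,8.5,10.0,9.0,8.2
Feather River,39.519,233,0.176,20.5,9.0,11.5,14.0,12.5,10.8,17.5,6.5,11.0,11.5,10.0,8.6
Priest Rapids,46.630,631,0.198,21.0,3.5,17.5,12.5,11.0,9.0,18.0,2.5,15.5,9.5,8.0,6.8
Trask River,45.433,28,0.607,17.0,7.0,10.0,11.5,10.5,9.2,15.0,6.0,9.0,10.5,9.5,8.4
Trinity River,40.727,250,2.248,18.5,5.5,13.0,10.5,9.5,7.5,13.0,3.0,10.0,8.0,6.5,5.0
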