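table,parameter,type,feature,icc,bound_first,bound_second,precision_printed
2,SM,local,entropy,0.97,0.95,0.98,1.5
2,SM,local,summation_entropy,0.81,0.70,0.88,9
2,SM,local,imc2,0.73,0.67,0.82,7.5
2,SM,local,mean,0.91,0.86,0.94,4
2,SM,local,idm,0.90,0.84,0.94,5
2,SM,local,id,0.85,0.72,0.92,10
2,SM,local,difference_entropy,0.84,0.75,0.89,7
2,SM,regional,rpc,0.92,0.84,0.92,4
2,SM,regional,sre,0.93,0.80,0.93,6.5
2,SM,regional,lre,0.89,0.78,0.89,5.5
2,SM,regional,hie,0.73,0.58,0.81,11.5
2,SM,shape_intensity,spherical_disproportionality,0.92,0.86,0.95,4.5
2,SM,shape_intensity,sphericity,0.91,0.85,0.94,4.5
2,SM,shape_intensity,intensity_entropy,0.85,0.79,0.92,6.5
2,SM,shape_intensity,convexity,0.70,0.59,0.82,11.5
4,GL,local,idm,0.96,0.93,0.98,2.5
4,GL,local,id,0.92,0.90,0.94,2
4,GL,local,imc2,0.72,0.65,0.90,12.5
4,GL,local,mean,0.85,0.82,0.94,6
4,GL,local,entropy,0.72,0.75,0.83,4
4,GL,local,summation_entropy,0.70,0.67,0.79,6
4,GL,local,difference_entropy,0.81,0.67,0.86,9.5
4,GL,regional,rpc,0.89,0.73,0.91,9
4,GL,regional,lre,0.72,0.64,0.87,11.5
4,GL,regional,sre,0.80,0.70,0.83,6.5
6,RA,local,idm,0.94,0.80,0.98,9
6,RA,local,id,0.97,0.90,0.99,4.5
6,RA,local,imc2,0.77,0.45,0.89,22
6,RA,local,mean,0.83,0.79,0.94,6.5
6,RA,local,entropy,0.84,0.68,0.96,14
6,RA,local,summation_entropy,0.84,0.70,0.96,13
6,RA,local,difference_entropy,0.78,0.76,0.95,9.5
6,RA,regional,rpc,0.90,0.74,0.97,11.5
6,RA,regional,lre,0.73,0.65,0.80,7.5
6,RA,regional,sre,0.82,0.73,0.94,10.5
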