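experiment,fluid,cohort,capture,stain,n_roi,mean,median,sem,cv
hepatocyte_plasma,plasma,test,MmCD81,mouse_panel,20,202,198,5.8,0.13
hepatocyte_plasma,plasma,test,MmCD81,hCD81,20,23.0,22.0,1.4,0.28
hepatocyte_plasma,plasma,test,HsCD81,mouse_panel,20,35.4,32.4,2.6,0.33
hepatocyte_plasma,plasma,test,HsCD81,hCD81,20,4.9,5.1,0.4,0.33
hepatocyte_plasma,plasma,control,MmCD81,mouse_panel,20,517,535,19.9,0.17
hepatocyte_plasma,plasma,control,MmCD81,hCD81,20,0.7,0.0,0.2,1.16
hepatocyte_plasma,plasma,control,HsCD81,mouse_panel,20,0.8,0.7,0.1,0.70
hepatocyte_plasma,plasma,control,HsCD81,hCD81,20,0.5,0.3,0.1,1.13
neuron_plasma,plasma,test,MmCD81,cocktail,20,259,254,7.1,0.12
neuron_plasma,plasma,test,HsCD81,cocktail,20,3.3,3.2,0.2,0.28
neuron_plasma,plasma,control,MmCD81,cocktail,20,648,654,29,0.20
neuron_plasma,plasma,control,HsCD81,cocktail,20,1.7,1.3,0.2,0.60
neuron_csf,CSF,test,MmCD81,cocktail,10,42,43,3.1,0.24
neuron_csf,CSF,test,HsCD81,cocktail,10,0.4,0.3,0.1,0.71
neuron_csf,CSF,control,MmCD81,cocktail,10,161,156,15,0.29
neuron_csf,CSF,control,HsCD81,cocktail,10,0.7,0.7,0.1,0.36
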