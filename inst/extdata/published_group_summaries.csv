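quantity,marker,tissue,group,mean,sem,n,units
iop_postinjection,NA,NA,VEHICLE_SALINE,20.12,2.69,6,mmHg
iop_postinjection,NA,NA,VEHICLE_MICROBEAD,26.69,2.73,6,mmHg
iop_postinjection,NA,NA,HE20_SALINE,20.37,2.68,6,mmHg
iop_postinjection,NA,NA,HE20_MICROBEAD,26.39,2.51,6,mmHg
iop_postinjection,NA,NA,HE100_SALINE,20.39,2.53,6,mmHg
iop_postinjection,NA,NA,HE100_MICROBEAD,26.49,2.52,6,mmHg
intact_transport,NA,SC,VEHICLE_SALINE,89.2,2.7,6,percent
intact_transport,NA,SC,VEHICLE_MICROBEAD,57.4,6.0,6,percent
intact_transport,NA,SC,HE20_SALINE,85.8,3.9,5,percent
intact_transport,NA,SC,HE20_MICROBEAD,71.9,9.8,5,percent
intact_transport,NA,SC,HE100_SALINE,90.9,3.7,5,percent
intact_transport,NA,SC,HE100_MICROBEAD,83.0,7.1,5,percent
mb_saline_ratio,BDNF,SC,VEHICLE,2.34,0.12,6,ratio
mb_saline_ratio,BDNF,SC,HE20,0.71,0.09,5,ratio
mb_saline_ratio,BDNF,SC,HE100,1.34,0.08,5,ratio
mb_saline_ratio,BDNF,ONH,VEHICLE,0.84,0.16,3,ratio
mb_saline_ratio,BDNF,ONH,HE20,1.43,0.20,3,ratio
mb_saline_ratio,BDNF,ONH,HE100,0.93,0.12,3,ratio
mb_saline_ratio,BDNF,RETINA,VEHICLE,0.17,0.04,3,ratio
mb_saline_ratio,BDNF,RETINA,HE20,0.64,0.05,3,ratio
mb_saline_ratio,BDNF,RETINA,HE100,1.00,0.05,3,ratio
mb_saline_ratio,IBA1,SC,VEHICLE,1.29,0.19,6,ratio
mb_saline_ratio,IBA1,SC,HE20,0.84,0.11,5,ratio
mb_saline_ratio,IBA1,SC,HE100,0.86,0.17,5,ratio
mb_saline_ratio,IBA1,ONH,VEHICLE,1.56,0.12,3,ratio
mb_saline_ratio,IBA1,ONH,HE20,0.27,0.03,3,ratio
mb_saline_ratio,IBA1,ONH,HE100,1.09,0.27,3,ratio
mb_saline_ratio,IBA1,RETINA,VEHICLE,1.42,0.04,3,ratio
mb_saline_ratio,IBA1,RETINA,HE20,1.09,0.08,3,ratio
mb_saline_ratio,IBA1,RETINA,HE100,0.99,0.07,3,ratio
mb_saline_ratio,IL6,SC,VEHICLE,0.55,0.08,6,ratio
mb_saline_ratio,IL6,SC,HE100,1.75,0.51,5,ratio
mb_saline_ratio,IL6,RETINA,VEHICLE,5.43,0.84,3,ratio
mb_saline_ratio,IL6,RETINA,HE20,2.10,0.37,3,ratio
mb_saline_ratio,IL6,RETINA,HE100,2.55,0.65,3,ratio
mb_saline_ratio,P75,ONH,VEHICLE,2.41,0.15,3,ratio
mb_saline_ratio,P75,ONH,HE20,1.02,0.14,3,ratio
mb_saline_ratio,P75,ONH,HE100,0.82,0.14,3,ratio
mb_saline_ratio,P75,RETINA,VEHICLE,2.41,0.22,3,ratio
mb_saline_ratio,P75,RETINA,HE20,1.53,0.20,3,ratio
mb_saline_ratio,P75,RETINA,HE100,1.26,0.21,3,ratio
mb_saline_ratio,APP,ONH,VEHICLE,12.13,1.49,3,ratio
mb_saline_ratio,APP,ONH,HE20,5.71,1.15,3,ratio
mb_saline_ratio,APP,ONH,HE100,5.63,0.84,3,ratio
mb_saline_ratio,APP,RETINA,VEHICLE,8.05,0.81,3,ratio
mb_saline_ratio,APP,RETINA,HE20,0.25,0.05,3,ratio
mb_saline_ratio,APP,RETINA,HE100,0.48,0.14,3,ratio
mb_saline_ratio,CP,RETINA,VEHICLE,4.61,0.49,3,ratio
mb_saline_ratio,CP,RETINA,HE20,0.92,0.29,3,ratio
mb_saline_ratio,CP,RETINA,HE100,0.18,0.03,3,ratio
mb_saline_ratio,IL1B,RETINA,VEHICLE,0.28,0.02,3,ratio
mb_saline_ratio,IL1B,RETINA,HE20,0.07,0.04,3,ratio
mb_saline_ratio,IL1B,RETINA,HE100,1.49,0.14,3,ratio
mb_saline_ratio,C1Q,RETINA,VEHICLE,1.225,0.061,3,ratio
mb_saline_ratio,C1Q,RETINA,HE20,1.430,0.096,3,ratio
mb_saline_ratio,C1Q,RETINA,HE100,0.037,0.007,3,ratio
mb_saline_ratio,TNFA,ONH,VEHICLE,1.68,0.20,3,ratio
mb_saline_ratio,TNFA,ONH,HE20,0.28,0.10,3,ratio
mb_saline_ratio,IL6RAM,ONH,VEHICLE,1.93,0.09,3,ratio
mb_saline_ratio,IL6RAM,ONH,HE20,0.72,0.03,3,ratio
mb_saline_ratio,IL6RAM,ONH,HE100,0.74,0.11,3,ratio
mb_saline_ratio,CD44,RETINA,VEHICLE,1.32,0.10,3,ratio
mb_saline_ratio,CD44,RETINA,HE100,0.48,0.11,3,ratio
mb_saline_ratio,ABETA,RETINA,VEHICLE,8.89,0.58,3,ratio
mb_saline_ratio,ABETA,RETINA,HE20,13.19,1.33,3,ratio
mb_saline_ratio,ABETA,RETINA,HE100,5.02,0.88,3,ratio
nuclear_nfkb_ratio,NFKB,SC,VEHICLE,0.71,0.5,5,ratio
nuclear_nfkb_ratio,NFKB,SC,HE20,1.25,0.09,5,ratio
nuclear_nfkb_ratio,NFKB,SC,HE100,0.99,0.09,5,ratio
nuclear_nfkb_ratio,NFKB,ONH,VEHICLE,1.50,0.18,5,ratio
nuclear_nfkb_ratio,NFKB,ONH,HE20,1.41,0.22,5,ratio
nuclear_nfkb_ratio,NFKB,ONH,HE100,0.97,0.12,5,ratio
nuclear_nfkb_ratio,NFKB,RETINA,VEHICLE,0.90,0.25,5,ratio
nuclear_nfkb_ratio,NFKB,RETINA,HE20,1.368,0.185,5,ratio
nuclear_nfkb_ratio,NFKB,RETINA,HE100,1.47,0.14,5,ratio
retinal_thickness,NA,RETINA,VEHICLE_SALINE,132.51,1.47,3,um
retinal_thickness,NA,RETINA,VEHICLE_MICROBEAD,130.93,1.99,3,um
retinal_thickness,NA,RETINA,HE20_SALINE,116.35,2.50,3,um
retinal_thickness,NA,RETINA,HE20_MICROBEAD,111.47,2.11,3,um
retinal_thickness,NA,RETINA,HE100_SALINE,87.70,0.59,3,um
retinal_thickness,NA,RETINA,HE100_MICROBEAD,96.91,0.98,3,um
inl_thickness,NA,RETINA,VEHICLE,16.8,0.3,3,um
inl_thickness,NA,RETINA,HE20,14.1,0.2,3,um
inl_thickness,NA,RETINA,HE100,13.2,0.1,3,um
onl_thickness,NA,RETINA,VEHICLE,33.6,0.4,3,um
onl_thickness,NA,RETINA,HE20,33.4,0.6,3,um
onl_thickness,NA,RETINA,HE100,27.1,0.2,3,um
rgc_density,NA,RETINA,VEHICLE,3.14e-4,6.91e-6,3,cells_per_um2
rgc_density,NA,RETINA,HE20,3.14e-4,7.77e-6,3,cells_per_um2
rgc_density,NA,RETINA,HE100,3.16e-4,7.48e-6,3,cells_per_um2
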