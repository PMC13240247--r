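range,season,predictor,coefficient,transform
Missisa,spring,prop_conifer,1,exponential
Missisa,spring,prop_peatland,1.6,exponential
Missisa,spring,prop_mixedwood,0.3,exponential
Missisa,spring,prop_water,-0.8,exponential
Missisa,spring,road_density,-4,exponential
Missisa,summer,prop_conifer,1.1,exponential
Missisa,summer,prop_peatland,1.55,exponential
Missisa,summer,prop_mixedwood,0.3,exponential
Missisa,summer,prop_water,-0.8,exponential
Missisa,summer,road_density,-3.5,exponential
Missisa,fall,prop_conifer,0.9,exponential
Missisa,fall,prop_peatland,1.65,exponential
Missisa,fall,prop_mixedwood,0.3,exponential
Missisa,fall,prop_water,-0.8,exponential
Missisa,fall,road_density,-1.2,exponential
Missisa,winter,prop_conifer,1.25,exponential
Missisa,winter,prop_peatland,1.475,exponential
Missisa,winter,prop_mixedwood,0.3,exponential
Missisa,winter,prop_water,-0.8,exponential
Missisa,winter,road_density,-0.6,exponential
JamesBay,spring,prop_conifer,0.7,exponential
JamesBay,spring,prop_peatland,1.9,exponential
JamesBay,spring,prop_mixedwood,0.1,exponential
JamesBay,spring,prop_water,-0.5,exponential
JamesBay,spring,road_density,-0.5,exponential
JamesBay,summer,prop_conifer,0.8,exponential
JamesBay,summer,prop_peatland,1.85,exponential
JamesBay,summer,prop_mixedwood,0.1,exponential
JamesBay,summer,prop_water,-0.5,exponential
JamesBay,summer,road_density,-0.4,exponential
JamesBay,fall,prop_conifer,0.6,exponential
JamesBay,fall,prop_peatland,1.95,exponential
JamesBay,fall,prop_mixedwood,0.1,exponential
JamesBay,fall,prop_water,-0.5,exponential
JamesBay,fall,road_density,-0.3,exponential
JamesBay,winter,prop_conifer,0.95,exponential
JamesBay,winter,prop_peatland,1.775,exponential
JamesBay,winter,prop_mixedwood,0.1,exponential
JamesBay,winter,prop_water,-0.5,exponential
JamesBay,winter,road_density,-0.2,exponential
Nipigon,spring,prop_conifer,1.8,exponential
Nipigon,spring,prop_peatland,0.6,exponential
Nipigon,spring,prop_mixedwood,0.8,exponential
Nipigon,spring,prop_water,-1,exponential
Nipigon,spring,road_density,-0.15,exponential
Nipigon,summer,prop_conifer,1.9,exponential
Nipigon,summer,prop_peatland,0.55,exponential
Nipigon,summer,prop_mixedwood,0.8,exponential
Nipigon,summer,prop_water,-1,exponential
Nipigon,summer,road_density,-0.1,exponential
Nipigon,fall,prop_conifer,1.7,exponential
Nipigon,fall,prop_peatland,0.65,exponential
Nipigon,fall,prop_mixedwood,0.8,exponential
Nipigon,fall,prop_water,-1,exponential
Nipigon,fall,road_density,-0.1,exponential
Nipigon,winter,prop_conifer,2.05,exponential
Nipigon,winter,prop_peatland,0.475,exponential
Nipigon,winter,prop_mixedwood,0.8,exponential
Nipigon,winter,prop_water,-1,exponential
Nipigon,winter,road_density,-0.05,exponential
Pagwachuan,spring,prop_conifer,1.5,exponential
Pagwachuan,spring,prop_peatland,0.9,exponential
Pagwachuan,spring,prop_mixedwood,0.6,exponential
Pagwachuan,spring,prop_water,-0.7,exponential
Pagwachuan,spring,road_density,-0.2,exponential
Pagwachuan,summer,prop_conifer,1.6,exponential
Pagwachuan,summer,prop_peatland,0.85,exponential
Pagwachuan,summer,prop_mixedwood,0.6,exponential
Pagwachuan,summer,prop_water,-0.7,exponential
Pagwachuan,summer,road_density,-0.15,exponential
Pagwachuan,fall,prop_conifer,1.4,exponential
Pagwachuan,fall,prop_peatland,0.95,exponential
Pagwachuan,fall,prop_mixedwood,0.6,exponential
Pagwachuan,fall,prop_water,-0.7,exponential
Pagwachuan,fall,road_density,-0.1,exponential
Pagwachuan,winter,prop_conifer,1.75,exponential
Pagwachuan,winter,prop_peatland,0.775,exponential
Pagwachuan,winter,prop_mixedwood,0.6,exponential
Pagwachuan,winter,prop_water,-0.7,exponential
Pagwachuan,winter,road_density,-0.05,exponential
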