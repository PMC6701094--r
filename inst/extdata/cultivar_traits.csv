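cultivar,youngs_modulus_mean,youngs_modulus_se,max_bending_load_mean,max_bending_load_se,max_transverse_displacement_mean,max_transverse_displacement_se,plant_height_mean,plant_height_se,plant_azimuthal_deviation_mean,plant_azimuthal_deviation_se,leaf_number_mean,leaf_number_se,leaf_inclination_angle_mean,leaf_inclination_angle_se,ear_number_mean,ear_number_se,ear_height_mean,ear_height_se,ear_length_mean,ear_length_se
ZD958,64.1,8.1,365.7,25.7,9.0,0.8,221.4,12.4,28.3,4.0,12.8,0.6,62.2,2.8,2.5,0.3,85.2,6.4,28.4,1.9
JD38,90.0,1.4,406.6,6.7,9.3,0.4,239.6,4.5,29.0,3.1,11.4,0.4,63.5,1.7,1.4,0.2,88.7,4.7,27.6,1.6
XD20,67.0,2.3,366.6,23.4,8.1,0.9,256.0,3.5,22.5,4.0,11.6,0.4,69.8,0.6,1.6,0.2,120.1,2.6,26.0,0.6
XY335,98.2,8.9,421.6,47.2,8.1,1.5,259.0,3.0,20.2,3.1,10.2,0.2,63.9,1.2,1.4,0.2,91.0,3.2,27.8,1.8
JK665,83.6,13.7,422.7,70.7,8.3,0.7,260.7,3.5,20.6,2.9,13.0,0.3,61.7,1.6,2.0,0.0,90.2,6.6,32.2,1.2
JK968,85.3,7.5,432.0,34.5,8.1,0.4,236.8,8.6,19.0,1.3,12.0,0.3,65.6,1.7,1.6,0.2,103.2,9.5,30.6,2.0
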