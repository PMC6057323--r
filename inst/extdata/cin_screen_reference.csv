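feature,p_raw,p_adj,r_pb,mean_low,se_low,mean_high,se_high
dwt2d_mean_absolute_deviation,4.48E-02,1.34E-01,-0.34,6.23,0.13,5.50,0.28
dwt2h_mean_absolute_deviation,2.02E-03,1.82E-02,-0.39,10.44,0.24,8.67,0.59
dwt2h_mean_value,6.25E-03,3.03E-02,0.27,-0.84,0.029,-0.68,0.080
dwt2h_median_absolute_deviation,7.20E-03,3.24E-02,-0.33,1.17,0.065,0.95,0.072
dwt2h_median_value,5.03E-05,3.17E-03,0.18,-0.014,0.0024,-0.0079,0.0048
dwt2h_standard_deviation,2.50E-02,7.87E-02,-0.31,23.33,0.39,20.80,1.10
gray_level_nonuniformity,2.02E-03,2.13E-02,0.52,85.21,1.98,116.83,7.71
kurtosis,2.98E-03,2.35E-02,0.37,2.59,0.02,2.71,0.04
local_binary_pattern_mean_value,1.02E-02,3.77E-02,0.40,16.61,0.23,18.03,0.45
local_binary_pattern_standard_deviation,1.37E-04,4.30E-03,-0.47,0.12,0.00082,0.12,0.0014
nucleus_area,7.20E-03,3.02E-02,0.46,1141,50,1640,137
nucleus_convex_area,8.27E-03,3.26E-02,0.45,1253,53,1772,147
nucleus_equivalent_diameter,5.03E-03,2.64E-02,0.47,36.53,0.78,43.59,1.85
nucleus_extent,5.00E-02,1.43E-01,0.22,0.64,0.0045,0.66,0.0079
nucleus_major_axis_length,1.16E-02,4.07E-02,0.37,52.6,1.7,60.1,2.3
nucleus_minor_axis_length,3.75E-03,2.36E-02,0.47,28.0,0.5,34.1,1.7
nucleus_perimeter,1.24E-02,4.12E-02,0.40,135.9,3.2,156.6,6.4
nucleus_solidity,1.37E-04,2.87E-03,0.52,0.91,0.0027,0.93,0.0037
tamura_coarseness_1,1.15E-03,1.81E-02,0.45,7.12,0.12,8.01,0.24
tamura_coarseness_2,4.04E-03,2.31E-02,0.48,23.88,0.57,33.99,2.77
tamura_coarseness_3,2.98E-03,2.09E-02,0.45,9.11,0.37,14.27,1.51
tamura_coarseness_4,1.73E-03,2.18E-02,0.49,18.21,0.70,23.94,1.40
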