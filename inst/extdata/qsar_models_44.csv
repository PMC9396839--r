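model,n_train,n_test,r2,r0sq,r0sq_rev,r0sq_unc,aae_train,sd_train,aae_test,sd_test,training_range,k,k_prime,ratio_fwd_rep,ratio_rev_rep,rm2_rep,ccc,p_value,p_below,aae3sd_rep,mult10_rep,mult20_rep,mult15_rep,mult25_rep,class_rep
1,39,10,0.917,0.909,0.917,0.999,0.161,0.114,0.221,0.110,4.07,1.00,1.00,0.010,0.000,0.83,0.95,0.14,FALSE,0.55,0.41,0.81,0.61,1.02,G
2,39,10,0.880,0.879,0.857,0.999,0.237,0.234,0.318,0.150,4.07,1.01,0.98,0.000,0.025,0.86,0.92,0.31,FALSE,0.77,0.41,0.81,0.61,1.02,G
3,31,10,0.715,0.715,0.617,0.997,0.167,0.171,0.266,0.244,1.72,1.00,1.00,0.000,0.138,0.71,0.84,0.18,FALSE,1.02,0.17,0.34,0.26,0.43,B
4,26,11,0.725,0.310,0.691,0.997,0.233,0.167,0.354,0.301,2.74,0.98,1.02,0.573,0.047,0.26,0.77,0.23,FALSE,1.26,0.27,0.55,0.41,0.69,B
5,40,10,0.906,0.904,0.904,0.999,0.121,0.091,0.206,0.095,2.68,1.00,1.00,0.002,0.003,0.86,0.95,0.01,FALSE,0.49,0.27,0.54,0.40,0.67,G
6,40,10,0.892,0.879,0.892,0.999,0.122,0.087,0.195,0.146,2.68,1.00,1.00,0.015,0.000,0.79,0.94,0.16,FALSE,0.63,0.27,0.54,0.40,0.67,M
7,68,17,0.261,0.012,0.052,0.957,0.503,0.435,1.165,0.715,5.00,0.98,0.98,0.956,0.800,0.13,0.51,0.01,TRUE,3.31,0.50,1.00,0.75,1.25,B
8,68,17,0.444,0.220,0.404,0.977,0.331,0.674,0.435,0.326,4.60,0.97,1.01,0.506,0.090,0.23,0.66,0.543,FALSE,1.41,0.46,0.92,0.69,1.15,B
9,42,11,0.834,0.823,0.818,0.824,0.872,0.678,1.630,1.256,14.46,0.74,1.11,0.014,0.020,0.75,0.89,0.08,FALSE,5.40,1.35,2.70,2.02,3.37,B
10,42,9,0.588,0.552,0.511,0.999,0.040,0.035,0.169,0.124,1.85,1.02,0.98,0.062,0.131,0.48,0.68,0.01,FALSE,0.54,0.19,0.37,0.28,0.46,B
11,42,9,0.748,0.496,0.730,0.999,0.053,0.043,0.133,0.077,1.85,0.98,1.02,0.336,0.024,0.37,0.75,0.01,FALSE,0.36,0.19,0.37,0.28,0.46,G
12,20,6,0.963,0.962,0.983,0.787,0.052,0.043,0.035,0.035,0.91,1.05,0.92,0.001,-0.021,0.93,0.97,0.41,FALSE,0.14,0.09,0.18,0.14,0.23,G
13,90,22,0.372,0.376,-0.292,0.950,0.432,0.648,0.538,0.647,6.95,1.00,0.95,-0.012,1.786,ND,0.57,0.49,FALSE,2.48,0.70,1.40,1.05,1.74,B
14,68,17,0.382,0.136,0.309,0.975,0.364,0.324,0.457,0.356,4.90,1.01,0.97,0.644,0.189,0.19,0.61,0.30,FALSE,1.53,0.49,0.98,0.74,1.23,B
15,27,5,0.088,-2.263,-1.129,0.995,0.074,0.094,0.315,0.135,0.40,1.02,0.97,26.745,13.844,-0.05,-0.25,0.01,TRUE,0.72,0.04,0.08,0.06,0.10,B
16,27,7,0.818,-1.721,0.563,0.993,0.412,0.352,0.645,0.489,3.76,1.05,0.95,3.105,0.312,-0.49,0.55,0.16,FALSE,2.11,0.38,0.75,0.56,0.94,B
17,27,7,0.763,-4.030,0.462,0.992,0.359,0.290,0.729,0.511,3.76,1.05,0.94,6.282,0.394,-0.91,0.43,0.02,FALSE,2.26,0.38,0.75,0.56,0.94,B
18,89,19,0.932,0.932,0.928,0.998,0.187,0.151,0.246,0.204,3.95,1.01,0.99,0.000,0.004,0.92,0.96,0.14,FALSE,0.80,0.40,0.79,0.59,0.99,M
19,89,19,0.821,0.813,0.811,0.995,0.255,0.186,0.339,0.368,3.95,1.01,0.98,0.009,0.012,0.75,0.90,0.34,FALSE,1.44,0.40,0.79,0.59,0.99,B
20,66,16,0.703,0.514,0.914,0.984,0.444,0.338,0.678,0.411,5.45,0.97,1.01,0.270,-0.300,0.40,0.81,0.02,FALSE,1.91,0.55,1.09,0.82,1.36,B
21,66,16,0.671,0.475,0.700,0.983,0.384,0.324,0.706,0.461,5.45,0.96,1.02,0.292,-0.044,0.37,0.79,0.02,FALSE,2.09,0.55,1.09,0.82,1.36,B
22,66,16,0.914,0.908,0.670,0.995,0.288,0.232,0.297,0.307,5.45,0.99,1.03,0.007,0.268,0.84,0.95,0.90,FALSE,1.22,0.55,1.09,0.82,1.36,M
23,32,11,0.790,0.006,0.683,0.993,0.120,0.094,0.501,0.249,4.68,0.91,1.09,0.992,0.136,0.09,0.60,0.01,TRUE,1.25,0.47,0.94,0.70,1.17,B
24,40,12,0.876,0.875,0.845,0.999,0.090,0.079,0.238,0.088,3.35,1.00,1.00,0.002,0.035,0.84,0.93,0.01,TRUE,0.50,0.34,0.67,0.50,0.84,G
25,40,12,0.866,0.814,0.861,0.999,0.079,0.084,0.205,0.140,3.35,0.99,1.01,0.059,0.005,0.67,0.92,0.01,FALSE,0.62,0.34,0.67,0.50,0.84,G
26,63,16,0.999,0.999,0.999,1.000,0.011,0.006,0.011,0.006,3.76,1.00,1.00,0.000,0.000,1.00,1.00,0.65,FALSE,0.03,0.38,0.75,0.58,0.94,G
27,40,4,0.960,0.693,0.863,1.000,0.155,0.118,0.178,0.105,4.25,0.98,1.02,0.278,0.101,0.46,0.83,0.72,FALSE,0.03,0.43,0.85,0.64,1.06,G
28,22,7,0.995,0.995,0.995,1.000,0.043,0.064,0.046,0.032,2.56,1.00,1.00,0.000,0.000,0.99,1.00,0.90,FALSE,0.14,0.26,0.51,0.38,0.64,G
29,22,7,0.971,0.971,0.971,0.999,0.101,0.127,0.097,0.097,2.56,1.00,1.00,0.000,0.000,0.96,0.99,0.93,FALSE,0.39,0.26,0.51,0.38,0.64,G
30,50,18,0.914,0.796,0.879,1.000,0.041,0.038,0.068,0.134,2.35,1.00,1.00,0.129,0.038,0.60,0.93,0.42,FALSE,0.47,0.24,0.47,0.35,0.59,M
31,50,18,0.994,0.993,0.992,1.000,0.031,0.028,0.026,0.028,2.35,1.00,1.00,0.002,0.002,0.96,1.00,0.51,FALSE,0.11,0.24,0.47,0.35,0.59,G
32,52,12,0.815,0.686,0.801,0.983,0.340,0.269,0.297,0.261,3.32,1.03,0.95,0.158,0.017,0.52,0.87,0.61,FALSE,1.09,0.33,0.66,0.50,0.83,B
33,58,6,0.964,0.949,0.958,1.000,0.051,0.048,0.127,0.117,2.90,1.01,0.99,0.016,0.006,0.85,0.96,0.18,FALSE,0.48,0.29,0.58,0.44,0.73,G
34,58,6,0.966,0.965,0.962,1.000,0.066,0.052,0.105,0.076,2.90,1.00,1.00,0.001,0.004,0.94,0.98,0.10,FALSE,0.33,0.29,0.58,0.44,0.73,G
35,47,16,0.899,0.878,0.898,0.999,0.195,0.117,0.186,0.153,2.16,1.02,0.98,0.023,0.001,0.77,0.91,0.81,FALSE,0.64,0.22,0.43,0.28,0.54,B
36,52,20,0.533,0.367,0.511,0.995,0.566,0.378,0.383,0.314,4.28,1.01,0.98,0.311,0.041,0.32,0.71,0.06,FALSE,1.33,0.43,0.86,0.64,1.07,B
37,52,20,0.659,0.533,0.657,0.997,0.554,0.521,0.327,0.230,4.28,1.00,1.00,0.191,0.003,0.43,0.80,0.07,FALSE,1.02,0.43,0.86,0.64,1.07,M
38,52,20,0.744,0.714,0.733,0.998,0.355,0.343,0.282,0.213,4.28,1.00,1.00,0.040,0.014,0.62,0.86,0.38,FALSE,0.92,0.43,0.86,0.64,1.07,M
39,52,20,0.815,0.785,0.814,0.998,0.290,0.358,0.246,0.181,4.28,1.01,0.99,0.037,0.001,0.67,0.89,0.50,FALSE,0.79,0.43,0.86,0.64,1.07,G
40,31,10,0.658,0.475,0.658,0.995,0.097,0.064,0.272,0.202,2.17,0.97,1.03,0.278,0.000,0.38,0.77,0.02,FALSE,0.88,0.22,0.43,0.33,0.54,B
41,68,8,0.898,0.865,0.935,0.999,0.125,0.110,0.204,0.151,4.03,0.99,1.01,0.037,-0.041,0.73,0.94,0.03,FALSE,0.66,0.40,0.81,0.60,1.01,G
42,68,8,0.855,0.702,0.828,0.998,0.199,0.115,0.270,0.148,4.03,1.00,1.00,0.179,0.032,0.52,0.89,0.06,FALSE,0.71,0.40,0.81,0.60,1.01,G
43,53,18,0.806,0.678,0.795,0.996,0.122,0.118,0.279,0.203,3.78,1.00,0.99,0.159,0.014,0.52,0.87,0.01,FALSE,0.89,0.38,0.76,0.55,0.95,M
44,53,18,0.676,0.109,0.640,0.993,0.329,0.271,0.362,0.276,3.78,0.99,1.00,0.838,0.053,0.17,0.74,0.66,FALSE,1.19,0.38,0.76,0.55,0.95,B
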