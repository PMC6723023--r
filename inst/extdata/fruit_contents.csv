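fruit,analyte,experimental_mean,cv_e,predicted_mean,cv_p
blackberry,TAC,1416.69,11.20,1413.00,0.85
andean_blueberry,TAC,2682.30,2.66,2761.24,5.74
naranjilla,TCC,57.93,6.05,58.42,2.36
tamarillo,TCC,123.18,4.65,133.67,1.95
goldenberry,TCC,65.21,10.84,64.93,3.10
araza,TCC,62.85,1.92,61.96,1.09
blackberry,TPC,6352.28,4.77,5995.62,3.38
andean_blueberry,TPC,7254.62,10.86,7315.73,2.22
naranjilla,TPC,897.58,6.32,912.50,2.02
tamarillo,TPC,1062.77,10.26,1055.45,0.72
goldenberry,TPC,259.93,11.61,233.68,3.24
araza,TPC,3507.79,13.97,3256.33,6.94
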