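metric,roi,stratum,population,n,mean_pct,sd_pct
SUVR,cortical,whole,all,237,1.06,1.30
SUVR,cortical,whole,noncarriers,159,0.77,1.08
SUVR,cortical,whole,carriers,78,1.63,1.53
SUVR,cortical,low,all,194,0.80,1.18
SUVR,cortical,low,noncarriers,146,0.69,0.99
SUVR,cortical,low,carriers,48,1.15,1.56
SUVR,cortical,intermediate,all,20,2.83,0.93
SUVR,cortical,intermediate,noncarriers,5,2.81,0.69
SUVR,cortical,intermediate,carriers,15,2.84,1.02
SUVR,cortical,high,all,23,1.77,1.18
SUVR,cortical,high,noncarriers,8,2.37,1.34
SUVR,cortical,high,carriers,15,1.98,1.07
SUVR,early,whole,all,237,1.25,1.26
SUVR,early,whole,noncarriers,159,0.99,1.08
SUVR,early,whole,carriers,78,1.75,1.44
SUVR,early,low,all,194,1.02,1.16
SUVR,early,low,noncarriers,146,0.91,1.03
SUVR,early,low,carriers,48,1.34,1.44
SUVR,early,intermediate,all,20,2.87,1.02
SUVR,early,intermediate,noncarriers,5,2.74,0.90
SUVR,early,intermediate,carriers,15,2.90,1.08
SUVR,early,high,all,23,1.74,1.13
SUVR,early,high,noncarriers,8,1.36,1.17
SUVR,early,high,carriers,15,1.94,1.09
DVR,cortical,whole,all,237,0.75,1.11
DVR,cortical,whole,noncarriers,159,0.50,0.91
DVR,cortical,whole,carriers,78,1.25,1.30
DVR,cortical,low,all,194,0.49,0.96
DVR,cortical,low,noncarriers,146,0.40,0.82
DVR,cortical,low,carriers,48,0.75,1.29
DVR,cortical,intermediate,all,20,2.34,0.72
DVR,cortical,intermediate,noncarriers,5,2.53,0.43
DVR,cortical,intermediate,carriers,15,2.34,0.80
DVR,cortical,high,all,23,1.55,0.93
DVR,cortical,high,noncarriers,8,1.16,1.07
DVR,cortical,high,carriers,15,1.76,0.80
DVR,early,whole,all,237,0.94,1.08
DVR,early,whole,noncarriers,159,0.72,0.94
DVR,early,whole,carriers,78,1.34,1.22
DVR,early,low,all,194,0.71,0.97
DVR,early,low,noncarriers,146,0.63,0.87
DVR,early,low,carriers,48,0.94,1.19
DVR,early,intermediate,all,20,2.49,0.76
DVR,early,intermediate,noncarriers,5,2.55,0.71
DVR,early,intermediate,carriers,15,2.47,0.80
DVR,early,high,all,23,1.50,0.89
DVR,early,high,noncarriers,8,1.15,0.96
DVR,early,high,carriers,15,1.68,0.83
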