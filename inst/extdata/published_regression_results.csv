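subject,pacing,target,predictors,r2,rmse,status
hfref,spontaneous,EDP,invPTT,0.776,0.588,ok
hfref,spontaneous,EDP,setAB_plus_invPTT,0.955,0.298,ok
hfref,spontaneous,ESP,invPTT,0.897,0.547,ok
hfref,spontaneous,ESP,setAB_plus_invPTT,0.944,0.458,ok
hfref,spontaneous,dPdt_max,invPTT,0.889,3.747,ok
hfref,spontaneous,dPdt_max,setAB_plus_invPTT,0.934,3.290,ok
healthy,spontaneous,EDP,invPTT,0.003,1.480,ok
healthy,spontaneous,EDP,setAB_plus_invPTT,0.189,1.595,ok
healthy,spontaneous,ESP,invPTT,0.006,1.112,ok
healthy,spontaneous,ESP,setAB_plus_invPTT,0.230,1.222,ok
healthy,spontaneous,dPdt_max,invPTT,0.000,7.647,ok
healthy,spontaneous,dPdt_max,setAB_plus_invPTT,0.340,7.415,ok
hfref,100bpm,EDP,invPTT,0.379,0.539,ok
hfref,100bpm,EDP,setAB_plus_invPTT,0.747,0.379,ok
hfref,120bpm,EDP,invPTT,0.485,0.415,ok
hfref,120bpm,EDP,setAB_plus_invPTT,0.724,0.329,ok
hfref,140bpm,EDP,invPTT,0.066,1.308,ok
hfref,140bpm,EDP,setAB_plus_invPTT,0.576,0.945,ok
hfref,160bpm,EDP,invPTT,0.310,2.928,ok
hfref,160bpm,EDP,setAB_plus_invPTT,0.849,1.455,ok
hfref,100bpm,ESP,invPTT,0.863,0.747,ok
hfref,100bpm,ESP,setAB_plus_invPTT,0.912,0.657,ok
hfref,120bpm,ESP,invPTT,0.854,0.596,ok
hfref,120bpm,ESP,setAB_plus_invPTT,0.912,0.502,ok
hfref,140bpm,ESP,invPTT,0.105,4.589,ok
hfref,140bpm,ESP,setAB_plus_invPTT,0.363,4.102,ok
hfref,160bpm,ESP,invPTT,0.893,1.674,ok
hfref,160bpm,ESP,setAB_plus_invPTT,0.918,1.804,ok
hfref,100bpm,dPdt_max,invPTT,0.859,8.175,ok
hfref,100bpm,dPdt_max,setAB_plus_invPTT,0.942,5.760,ok
hfref,120bpm,dPdt_max,invPTT,0.843,10.905,ok
hfref,120bpm,dPdt_max,setAB_plus_invPTT,0.933,7.736,ok
hfref,140bpm,dPdt_max,invPTT,0.053,117.579,ok
hfref,140bpm,dPdt_max,setAB_plus_invPTT,0.797,58.025,ok
hfref,160bpm,dPdt_max,invPTT,0.900,45.350,ok
hfref,160bpm,dPdt_max,setAB_plus_invPTT,0.954,32.842,ok
healthy,100bpm,EDP,invPTT,0.497,0.801,ok
healthy,100bpm,EDP,setAB_plus_invPTT,0.694,0.820,ok
healthy,120bpm,EDP,invPTT,0.002,1.139,ok
healthy,120bpm,EDP,setAB_plus_invPTT,0.690,0.699,ok
healthy,140bpm,EDP,invPTT,0.547,0.961,ok
healthy,140bpm,EDP,setAB_plus_invPTT,0.900,0.580,ok
healthy,160bpm,EDP,invPTT,0.131,4.640,ok
healthy,160bpm,EDP,setAB_plus_invPTT,NA,NA,not_available
healthy,100bpm,ESP,invPTT,0.448,0.830,ok
healthy,100bpm,ESP,setAB_plus_invPTT,0.806,0.661,ok
healthy,120bpm,ESP,invPTT,0.017,0.932,ok
healthy,120bpm,ESP,setAB_plus_invPTT,0.230,0.907,ok
healthy,140bpm,ESP,invPTT,0.744,0.498,ok
healthy,140bpm,ESP,setAB_plus_invPTT,0.884,0.425,ok
healthy,160bpm,ESP,invPTT,0.823,2.736,ok
healthy,160bpm,ESP,setAB_plus_invPTT,NA,NA,not_available
healthy,100bpm,dPdt_max,invPTT,0.000,130.251,ok
healthy,100bpm,dPdt_max,setAB_plus_invPTT,0.512,11.648,ok
healthy,120bpm,dPdt_max,invPTT,0.026,29.865,ok
healthy,120bpm,dPdt_max,setAB_plus_invPTT,0.249,28.846,ok
healthy,140bpm,dPdt_max,invPTT,0.371,26.943,ok
healthy,140bpm,dPdt_max,setAB_plus_invPTT,0.803,19.249,ok
healthy,160bpm,dPdt_max,invPTT,0.969,52.621,ok
healthy,160bpm,dPdt_max,setAB_plus_invPTT,NA,NA,not_available
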