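"muscle","point_index","segment","x","y","z","pcsa","group"
"deltoideus_clavicular",1,"clavicle",0.025,0.042,0.018,8,"deltoid"
"deltoideus_clavicular",2,"humerus",0.006,-0.12,0.01,8,"deltoid"
"deltoideus_scapular",1,"scapula",-0.005,0.045,0.03,20,"deltoid"
"deltoideus_scapular",2,"humerus",0,-0.13,0.012,20,"deltoid"
"supraspinatus",1,"scapula",0,0.022,-0.045,6,"rotator_cuff"
"supraspinatus",2,"humerus",0,0.012,0.021,6,"rotator_cuff"
"infraspinatus",1,"scapula",-0.03,-0.005,-0.048,9,"rotator_cuff"
"infraspinatus",2,"humerus",-0.014,0.004,0.018,9,"rotator_cuff"
"subscapularis",1,"scapula",0.03,-0.008,-0.018,16,"rotator_cuff"
"subscapularis",2,"humerus",0.019,0.012,0.012,16,"rotator_cuff"
"teres_minor",1,"scapula",-0.026,-0.038,-0.042,3,"rotator_cuff"
"teres_minor",2,"humerus",-0.012,-0.01,0.016,3,"rotator_cuff"
"pectoralis_major",1,"thorax",0.05,-0.03,-0.06,12,"other"
"pectoralis_major",2,"humerus",0.008,-0.05,0.008,12,"other"
"latissimus_dorsi",1,"thorax",-0.04,-0.09,-0.06,10,"other"
"latissimus_dorsi",2,"humerus",0.004,-0.045,0.006,10,"other"
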