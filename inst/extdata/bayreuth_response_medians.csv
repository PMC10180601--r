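species,index,w,event,value
C. libani,rs,1,2003,0.72
C. libani,rs,1,2012,0.77
C. libani,rs,1,2015,0.95
C. libani,rs,1,2018,0.95
C. libani,rs,1,avg,0.88
P. abies,rs,1,2003,0.46
P. abies,rs,1,2012,0.68
P. abies,rs,1,2015,0.88
P. abies,rs,1,2018,0.55
P. abies,rs,1,avg,0.65
P. sylvestris,rs,1,2003,0.70
P. sylvestris,rs,1,2012,1.05
P. sylvestris,rs,1,2015,0.79
P. sylvestris,rs,1,2018,0.65
P. sylvestris,rs,1,avg,0.74
C. libani,rs,2,2003,0.72
C. libani,rs,2,2012,0.78
C. libani,rs,2,2015,0.93
C. libani,rs,2,avg,0.79
P. abies,rs,2,2003,0.53
P. abies,rs,2,2012,0.75
P. abies,rs,2,2015,0.76
P. abies,rs,2,avg,0.71
P. sylvestris,rs,2,2003,0.71
P. sylvestris,rs,2,2012,1.12
P. sylvestris,rs,2,2015,0.81
P. sylvestris,rs,2,avg,0.81
C. libani,rc,1,2003,1.74
C. libani,rc,1,2012,1.22
C. libani,rc,1,2015,1.24
C. libani,rc,1,2018,1.26
C. libani,rc,1,avg,1.31
P. abies,rc,1,2003,1.11
P. abies,rc,1,2012,0.77
P. abies,rc,1,2015,1.69
P. abies,rc,1,2018,0.87
P. abies,rc,1,avg,1.02
P. sylvestris,rc,1,2003,1.37
P. sylvestris,rc,1,2012,0.77
P. sylvestris,rc,1,2015,0.98
P. sylvestris,rc,1,2018,1.05
P. sylvestris,rc,1,avg,1.04
C. libani,rc,2,2003,1.68
C. libani,rc,2,2012,1.12
C. libani,rc,2,2015,1.07
C. libani,rc,2,avg,1.24
P. abies,rc,2,2003,1.33
P. abies,rc,2,2012,0.64
P. abies,rc,2,2015,1.63
P. abies,rc,2,avg,1.24
P. sylvestris,rc,2,2003,1.44
P. sylvestris,rc,2,2012,0.77
P. sylvestris,rc,2,2015,1.28
P. sylvestris,rc,2,avg,1.17
C. libani,rl,1,2003,1.29
C. libani,rl,1,2012,0.93
C. libani,rl,1,2015,1.26
C. libani,rl,1,2018,1.16
C. libani,rl,1,avg,1.14
P. abies,rl,1,2003,0.52
P. abies,rl,1,2012,0.56
P. abies,rl,1,2015,1.58
P. abies,rl,1,2018,0.54
P. abies,rl,1,avg,0.60
P. sylvestris,rl,1,2003,0.90
P. sylvestris,rl,1,2012,0.74
P. sylvestris,rl,1,2015,0.73
P. sylvestris,rl,1,2018,0.64
P. sylvestris,rl,1,avg,0.74
C. libani,rl,2,2003,1.08
C. libani,rl,2,2012,0.88
C. libani,rl,2,2015,1.01
C. libani,rl,2,avg,0.97
P. abies,rl,2,2003,0.74
P. abies,rl,2,2012,0.53
P. abies,rl,2,2015,1.26
P. abies,rl,2,avg,0.74
P. sylvestris,rl,2,2003,0.94
P. sylvestris,rl,2,2012,0.78
P. sylvestris,rl,2,2015,0.85
P. sylvestris,rl,2,avg,0.87
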