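phrase,met,team_sport
walking,3.5,FALSE
running,8.0,FALSE
jogging,7.0,FALSE
dancing,4.5,FALSE
hiking,6.0,FALSE
yoga,2.5,FALSE
swimming,7.0,FALSE
cycling,7.5,FALSE
treadmill,6.0,FALSE
weight lifting,3.0,FALSE
gardening,3.8,FALSE
pilates,3.0,FALSE
zumba,6.5,FALSE
climbing,7.5,FALSE
rowing,7.0,FALSE
skiing,7.0,FALSE
skating,7.0,FALSE
surfing,3.0,FALSE
golf,4.8,FALSE
tennis,7.3,FALSE
basketball,6.5,TRUE
soccer,7.0,TRUE
baseball,5.0,TRUE
football,8.0,TRUE
volleyball,4.0,TRUE
hockey,8.0,TRUE
softball,5.0,TRUE
scuba diving,7.0,FALSE
jumping rope,11.0,FALSE
kickboxing,7.5,FALSE
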