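pig_id,pulse_type,exposure,location_id,ebd,mri,macroscopic_damage,histology_grade,subharmonic
3,SINE,FIXED,,Y,,Y,3,Y
4,SINE,FIXED,,Y,,Y,3,Y
4,SBPK,FIXED,,Y,,N,2,Y
5,SBPK,RAMP,1,Y,,N,1,Y
5,SBPK,RAMP,2,Y,,N,1,Y
6,SBPK,RAMP,1,Y,,N,,Y
6,SBPK,RAMP,2,Y,,N,,Y
6,SBPK,RAMP,3,N,,N,,N
6,SBPK,RAMP,4,Y,,N,,Y
7,SBPK,RAMP,1,Y,,N,,
7,SBPK,RAMP,2,N,,N,,N
7,SBPK,RAMP,3,N,,N,,Y
7,SBPK,RAMP,4,Y,,N,,Y
7,SBPK,RAMP,5,Y,,N,,Y
7,SBPK,RAMP,6,N,,N,,Y
7,SBPK,RAMP,7,N,,N,,N
7,SBPK,RAMP,8,Y,,N,,Y
8,SBPK,RAMP,1,N,N,N,2,Y
8,SBPK,RAMP,2,Y,Y,N,1,Y
8,SBPK,RAMP,3,Y,Y,N,1,Y
8,SBPK,RAMP,4,N,N,N,1,Y
8,SBPK,RAMP,5,Y,Y,Y,3,Y
8,SBPK,RAMP,6,N,Y,N,3,Y
8,SBPK,RAMP,7,Y,Y,Y,3,Y
8,SBPK,RAMP,8,Y,Y,N,2,Y
8,SBPK,RAMP,9,Y,Y,N,2,Y
8,SBPK,RAMP,10,Y,Y,Y,3,Y
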