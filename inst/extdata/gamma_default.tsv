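# gamma table: reference R=6 d=45 w=30
# provenance: V=10, eps_m=80, eps_c=120, youngs_modulus=100, poisson=0.49, regime=plane_stress, shapes=rectangular/rectangular, n_R=16, traction_mode=peak
R_um	d_um	w_um	gamma
4	20	10	 5.4510590502
6	20	10	 7.0812649779
8	20	10	10.5384984012
4	45	10	 0.7035739994
6	45	10	 0.7571024523
8	45	10	 0.8507129046
4	70	10	 0.2494649314
6	70	10	 0.2535406701
8	70	10	 0.2708839868
4	20	30	 5.6269353884
6	20	30	 6.1807311455
8	20	30	 7.7988029028
4	45	30	 0.9550302910
6	45	30	 1.0000000000
8	45	30	 1.0653698726
4	70	30	 0.3416390622
6	70	30	 0.3469539463
8	70	30	 0.3650721632
4	20	50	 5.6167310333
6	20	50	 6.1153320232
8	20	50	 7.6272657076
4	45	50	 1.0300744228
6	45	50	 1.0558573946
8	45	50	 1.0914136454
4	70	50	 0.3922672482
6	70	50	 0.3942932798
8	70	50	 0.4092911779
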