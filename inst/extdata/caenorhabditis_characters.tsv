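taxon	reproductive_mode	spicule_shape	spicule_curvature	spicule_tip	fan_shape	fan_anterior	fan_edge	terminal_notch	ray23_space	mid_dorsal_ray	short_ray4	precloacal_lip	phasmid	mating_position	rnai_response
C_elegans	hermaphroditic	long	even	simple	heart	closed	serrated	present	small	pos5	absent	hook	pore	parallel	competent
C_briggsae	hermaphroditic	long	even	simple	heart	closed	serrated	present	small	pos5	absent	hook	pore	parallel	incompetent
C_sp9	gonochoristic	long	even	simple	heart	closed	serrated	present	small	pos5	absent	hook	pore	parallel	incompetent
C_sp5	gonochoristic	long	even	simple	heart	closed	serrated	present	small	pos5	absent	hook	pore	parallel	incompetent
C_remanei	gonochoristic	long	even	simple	heart	closed	serrated	present	small	pos5	absent	hook	pore	parallel	incompetent
C_brenneri	gonochoristic	long	even	simple	heart	closed	serrated	present	small	pos5	absent	hook	pore	parallel	incompetent
C_sp10	gonochoristic	long	even	simple	heart	closed	serrated	present	small	pos5	absent	hook	pore	parallel	incompetent
C_sp11	hermaphroditic	long	even	simple	heart	closed	serrated	present	small	pos5	absent	hook	pore	parallel	incompetent
C_sp16	gonochoristic	long	even	simple	heart	closed	serrated	present	small	pos5	absent	hook	pore	parallel	incompetent
C_sp15	gonochoristic	long	angular	simple	heart	closed	serrated	present	small	pos5	absent	hook	pore	parallel	competent
C_japonica	gonochoristic	long	angular	complex	heart	closed	serrated	present	small	pos5	present	hook	pore	parallel	competent
C_sp7	gonochoristic	long	angular	complex	heart	closed	serrated	present	small	pos5	absent	hook	pore	parallel	competent
C_sp14	gonochoristic	long	even	simple	heart	closed	serrated	present	small	pos5	present	hook	pore	parallel	competent
C_sp17	gonochoristic	long	angular	simple	heart	closed	serrated	present	small	pos5	present	hook	pore	parallel	incompetent
C_sp18	gonochoristic	long	angular	simple	heart	closed	serrated	present	small	pos5	absent	hook	pore	parallel	incompetent
C_sp19	gonochoristic	long	angular	simple	heart	closed	serrated	present	small	pos5	present	hook	pore	parallel	incompetent
C_sp20	gonochoristic	long	angular	complex	heart	closed	serrated	absent	large	pos4	absent	hook	pore	parallel	competent
C_sp6	gonochoristic	long	angular	complex	heart	closed	serrated	absent	large	pos4	absent	hook	pore	parallel	competent
C_sp13	gonochoristic	long	angular	complex	other	closed	serrated	absent	large	pos4	absent	plain	pore	parallel	competent
C_drosophilae	gonochoristic	short	angular	complex	other	open	smooth	absent	large	pos4	absent	plain	pore	parallel	incompetent
C_sp2	gonochoristic	short	angular	complex	other	open	smooth	absent	large	pos4	absent	plain	pore	parallel	incompetent
C_angaria	gonochoristic	short	angular	complex	other	open	smooth	absent	large	pos4	absent	plain	papilliform	spiral	incompetent
C_sp8	gonochoristic	short	angular	complex	other	open	smooth	absent	large	pos4	absent	plain	papilliform	spiral	incompetent
C_sp12	gonochoristic	short	angular	complex	other	open	smooth	absent	large	pos4	absent	plain	papilliform	spiral	incompetent
C_sp1	gonochoristic	short	angular	complex	other	open	smooth	absent	large	pos5	absent	plain	pore	parallel	?
C_plicata	gonochoristic	long	angular	complex	other	open	smooth	absent	large	pos4	absent	plain	pore	parallel	incompetent
Protorhabditis_sp	gonochoristic	short	angular	complex	other	open	smooth	absent	large	pos5	absent	plain	pore	parallel	?
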