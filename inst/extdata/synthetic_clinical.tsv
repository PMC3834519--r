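sample	relapse	gender	tumor_grade	tumor_stage	vital_status	age_group	lymph_nodes	glucose	bilirubin	crp	creatinine	bmi	localization
S001	Yes	Male	Grade 2	I	Alive	<=40	10-20	60-100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Underweight	Sigmoid colon
S002	Yes	Male	Grade 2	I	Alive	41-55	10-20	60-100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Normal	Sigmoid colon
S003	Yes	Male	Grade 2	I	Alive	41-55	10-20	60-100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Normal	Sigmoid colon
S004	Yes	Male	Grade 2	I	Alive	41-55	10-20	60-100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Normal	Sigmoid colon
S005	Yes	Male	Grade 2	I	Alive	56-70	10-20	60-100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Normal	Sigmoid colon
S006	Yes	Male	Grade 2	I	Alive	56-70	10-20	60-100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Normal	Sigmoid colon
S007	Yes	Male	Grade 2	I	Alive	56-70	10-20	60-100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Normal	Sigmoid colon
S008	Yes	Male	Grade 2	I	Alive	56-70	10-20	60-100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Normal	Sigmoid colon
S009	Yes	Male	Grade 2	I	Alive	56-70	10-20	60-100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Normal	Sigmoid colon
S010	Yes	Male	Grade 2	I	Alive	56-70	10-20	60-100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Normal	Sigmoid colon
S011	Yes	Male	Grade 2	I	Alive	56-70	10-20	60-100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Normal	Sigmoid colon
S012	Yes	Male	Grade 2	I	Alive	56-70	10-20	60-100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Normal	Sigmoid colon
S013	Yes	Male	Grade 2	II	Alive	56-70	10-20	60-100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Normal	Sigmoid colon
S014	Yes	Male	Grade 2	II	Alive	56-70	10-20	60-100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Normal	Sigmoid colon
S015	Yes	Male	Grade 2	II	Alive	56-70	10-20	60-100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Normal	Ileocaecal
S016	Yes	Male	Grade 2	II	Alive	56-70	10-20	60-100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Normal	Ileocaecal
S017	Yes	Male	Grade 2	II	Alive	56-70	10-20	60-100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Normal	Ileocaecal
S018	Yes	Male	Grade 2	II	Alive	56-70	10-20	60-100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Normal	Ileocaecal
S019	Yes	Male	Grade 2	II	Alive	56-70	10-20	60-100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Overweight	Left flexure
S020	Yes	Male	Grade 2	II	Alive	56-70	20-30	60-100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Overweight	Rectum
S021	No	Male	Grade 2	II	Alive	56-70	20-30	60-100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Overweight	Rectum
S022	No	Male	Grade 2	II	Alive	56-70	20-30	>100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Overweight	Rectum
S023	No	Female	Grade 2	II	Alive	56-70	20-30	>100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Overweight	Rectum
S024	No	Female	Grade 2	II	Alive	56-70	20-30	>100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Overweight	Rectum
S025	No	Female	Grade 2	II	Alive	56-70	20-30	>100 mg/dl	<=1.1 mg/dl	<=5 mg/l	<=1.1 mg/dl	Overweight	Rectum
S026	No	Female	Grade 2	II	Alive	56-70	20-30	>100 mg/dl	<=1.1 mg/dl	>5 mg/l	<=1.1 mg/dl	Overweight	Rectum
S027	No	Female	Grade 2	II	Alive	56-70	20-30	>100 mg/dl	<=1.1 mg/dl	>5 mg/l	<=1.1 mg/dl	Overweight	Rectum
S028	No	Female	Grade 2	II	Alive	56-70	20-30	>100 mg/dl	<=1.1 mg/dl	>5 mg/l	<=1.1 mg/dl	Overweight	Rectum
S029	No	Female	Grade 2	II	Alive	56-70	30-40	>100 mg/dl	<=1.1 mg/dl	>5 mg/l	<=1.1 mg/dl	Overweight	Rectum
S030	No	Female	Grade 2	II	Alive	>70	30-40	>100 mg/dl	<=1.1 mg/dl	>5 mg/l	<=1.1 mg/dl	Overweight	Rectum
S031	No	Female	Grade 2	II	Alive	>70	30-40	>100 mg/dl	<=1.1 mg/dl	>5 mg/l	<=1.1 mg/dl	Obese	Rectum
S032	No	Female	Grade 2	II	Alive	>70	30-40	Unknown	<=1.1 mg/dl	>5 mg/l	<=1.1 mg/dl	Obese	Rectum
S033	No	Female	Grade 2	II	Alive	>70	30-40	Unknown	<=1.1 mg/dl	>5 mg/l	>1.1 mg/dl	Obese	Rectum
S034	No	Female	Grade 3	II	Alive	>70	30-40	Unknown	<=1.1 mg/dl	>5 mg/l	>1.1 mg/dl	Obese	Transverse colon
S035	No	Female	Grade 3	II	Alive	>70	40-50	Unknown	<=1.1 mg/dl	>5 mg/l	>1.1 mg/dl	Obese	Transverse colon
S036	No	Female	Grade 3	II	Alive	>70	40-50	Unknown	<=1.1 mg/dl	>5 mg/l	>1.1 mg/dl	Obese	Ascending colon
S037	No	Female	Grade 3	IIA	Dead	>70	40-50	Unknown	>1.1 mg/dl	Unknown	Unknown	Obese	Ascending colon
S038	No	Female	Grade 3	IIA	Dead	>70	50-60	Unknown	Unknown	Unknown	Unknown	Obese	Ascending colon
S039	No	Female	Grade 3	IIA	Dead	>70	50-60	Unknown	Unknown	Unknown	Unknown	Obese	Ascending colon
S040	No	Female	Grade 3	IIA	Dead	>70	50-60	Unknown	Unknown	Unknown	Unknown	Obese	Ascending colon
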