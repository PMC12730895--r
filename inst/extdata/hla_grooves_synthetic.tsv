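allele	groove_seq
A*01:01	LSHTVIQRQVRGDPWIRQHPQYVC
A*02:01	LRFTVIQRQVRGDPWIDQHPQMAY
A*03:01	SLFYIIQTQVRGDPWIRQHPQMVD
A*11:01	SLFTVIQRQVGGDMWIRQHPQSVC
A*24:02	SCVTVIQRQSFGDPWDRQHPQYVC
B*07:02	VDAQMPIHFTYPVKPYDYRDMNET
B*08:01	TDYQMPSHFRSPVMTYDYRDMNWQ
B*15:01	TDYQMPIHFTYGVKTYDYRDLFWT
B*35:01	TDYQMKRQFTYPTKTYDYRDMNWT
B*44:02	TDYQMPIWFTYPFDTMAYRDNNWG
C*03:04	EFWQKRGDERMPTKRFTEAYIEMH
C*04:01	EFKDKRGDFRVPTKFFWEYYIIMS
C*05:01	EFKVKRGDFFVPTHRVTEDYHPMH
C*06:02	EAKQKRGDKRVPTKRFTFWYCIMH
C*07:01	EFKQWRGDERVFTKRFTEMYSIPH
C*07:02	EEKQKRGDFRHPLERFTEWGIIMH
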