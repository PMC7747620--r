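variable	category	n
age	>=60	61
age	<60	232
age	N/A	1
stage	I	160
stage	II	65
stage	III	42
stage	IV	21
stage	N/A	6
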