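{"spacing_x_um":5,"spacing_y_um":5,"origin_x_um":0,"origin_y_um":0}
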