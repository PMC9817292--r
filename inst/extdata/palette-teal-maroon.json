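["#7F2704", "#C46A4A", "#F2F2F2", "#4AA3A0", "#00474F"]
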