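n2p:
- (instructed|reviewed|discussed).*(use\sof\sMDI|use\sof\sspacer|use\sof\snebulizer|use\sof\sinhaler)
p2n:
- trigger: (discussed|discussion)
  blocker: technique
blocker_mode: stem
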