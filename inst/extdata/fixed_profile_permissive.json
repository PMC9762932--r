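{
  "name": "permissive",
  "high": {
    "PVS1": "auto",
    "PS1": "false",
    "PS2": "false",
    "PS3": "false",
    "PS4": "false",
    "PM1": "false",
    "PM2": "auto",
    "PM3": "false",
    "PM4": "auto",
    "PM5": "false",
    "PM6": "false",
    "PP1": "true",
    "PP2": "true",
    "PP3": "auto",
    "PP4": "true",
    "PP5": "true",
    "BA1": "auto",
    "BS1": "auto",
    "BS2": "false",
    "BS3": "false",
    "BS4": "false",
    "BP1": "false",
    "BP2": "false",
    "BP3": "false",
    "BP4": "auto",
    "BP5": "false",
    "BP6": "false",
    "BP7": "false"
  },
  "moderate": {
    "PVS1": "auto",
    "PS1": "false",
    "PS2": "false",
    "PS3": "false",
    "PS4": "false",
    "PM1": "false",
    "PM2": "auto",
    "PM3": "false",
    "PM4": "auto",
    "PM5": "false",
    "PM6": "false",
    "PP1": "false",
    "PP2": "false",
    "PP3": "auto",
    "PP4": "false",
    "PP5": "false",
    "BA1": "auto",
    "BS1": "auto",
    "BS2": "false",
    "BS3": "false",
    "BS4": "false",
    "BP1": "false",
    "BP2": "false",
    "BP3": "false",
    "BP4": "auto",
    "BP5": "false",
    "BP6": "false",
    "BP7": "false"
  }
}
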