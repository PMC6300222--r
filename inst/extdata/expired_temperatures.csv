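taxon,model,flow,expired_temp_c
panoplosaurus,BB,high,22.67
panoplosaurus,BB,low,20.46
panoplosaurus,ST,high,21.57
panoplosaurus,ST,low,19.48
panoplosaurus,basic,low,26.5
panoplosaurus,straightened,low,23.93
euoplocephalus,BB,high,21.11
euoplocephalus,BB,low,19.42
euoplocephalus,ST,high,17.34
euoplocephalus,ST,low,15.87
euoplocephalus,basic,low,30.3
euoplocephalus,straightened,low,22.77
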