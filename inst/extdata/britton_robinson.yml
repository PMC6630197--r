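# Britton-Robinson universal buffer (flat key-value config)
# 0.04 M acetic + phosphoric + boric acid, 100 mL, titrated with 0.2 M NaOH
acid.acetic.conc: 0.04
acid.acetic.pKa: 4.756
acid.phosphoric.conc: 0.04
acid.phosphoric.pKa: 2.148, 7.198, 12.35
acid.boric.conc: 0.04
acid.boric.pKa: 9.237
initial_volume: 100
titrant_concentration: 0.2
titrant_volume: 0
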