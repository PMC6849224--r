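# Default metabolic indicator definitions: 11 class sums, 11 class
# ratios, 25 lipid-pair ratios (47 total). The set is a reconstruction:
# it contains the six indicators named in the literature on this panel
# (total lysoPC, total SM, total SM / total PC, the two lysoPC
# desaturation-pair ratios, dicarboxyl-AC / total AC) completed with
# per-class/bond-type sums and biochemically standard pair ratios
# (one double-bond or chain-modification steps). Selector syntax:
# "class:<classes>[;bond:...][;moiety:...][;db_min:n][;db_max:n]".

# ---- class sums (11) ----
- name: Total PC
  kind: class_sum
  numerator: "class:PC"
- name: Total PC aa
  kind: class_sum
  numerator: "class:PC;bond:aa"
- name: Total PC ae
  kind: class_sum
  numerator: "class:PC;bond:ae"
- name: Total lysoPC
  kind: class_sum
  numerator: "class:lysoPC"
- name: Total SM
  kind: class_sum
  numerator: "class:SM,SM(OH)"
- name: Total SM (OH)
  kind: class_sum
  numerator: "class:SM(OH)"
- name: Total AC
  kind: class_sum
  numerator: "class:AC"
- name: Total AC-DC
  kind: class_sum
  numerator: "class:AC;moiety:DC"
- name: Total AC-OH
  kind: class_sum
  numerator: "class:AC;moiety:OH"
- name: Total saturated PC
  kind: class_sum
  numerator: "class:PC;db_max:0"
- name: Total polyunsaturated PC
  kind: class_sum
  numerator: "class:PC;db_min:2"

# ---- class ratios (11) ----
- name: Total SM / Total PC
  kind: class_ratio
  numerator: "class:SM,SM(OH)"
  denominator: "class:PC"
- name: Total lysoPC / Total PC
  kind: class_ratio
  numerator: "class:lysoPC"
  denominator: "class:PC"
- name: Total SM (OH) / Total SM
  kind: class_ratio
  numerator: "class:SM(OH)"
  denominator: "class:SM,SM(OH)"
- name: Total PC ae / Total PC aa
  kind: class_ratio
  numerator: "class:PC;bond:ae"
  denominator: "class:PC;bond:aa"
- name: Total AC-DC / Total AC
  kind: class_ratio
  numerator: "class:AC;moiety:DC"
  denominator: "class:AC"
- name: Total AC-OH / Total AC
  kind: class_ratio
  numerator: "class:AC;moiety:OH"
  denominator: "class:AC"
- name: Total lysoPC / Total SM
  kind: class_ratio
  numerator: "class:lysoPC"
  denominator: "class:SM,SM(OH)"
- name: Total AC / Total PC
  kind: class_ratio
  numerator: "class:AC"
  denominator: "class:PC"
- name: Total polyunsaturated PC / Total saturated PC
  kind: class_ratio
  numerator: "class:PC;db_min:2"
  denominator: "class:PC;db_max:0"
- name: Total lysoPC / Total AC
  kind: class_ratio
  numerator: "class:lysoPC"
  denominator: "class:AC"
- name: Total SM / Total AC
  kind: class_ratio
  numerator: "class:SM,SM(OH)"
  denominator: "class:AC"

# ---- lipid-pair ratios (25) ----
- name: lysoPC a C16:0 / lysoPC a C16:1
  kind: pair_ratio
  numerator: "lysoPC a C16:0"
  denominator: "lysoPC a C16:1"
- name: lysoPC a C20:4 / lysoPC a C20:3
  kind: pair_ratio
  numerator: "lysoPC a C20:4"
  denominator: "lysoPC a C20:3"
- name: lysoPC a C16:0 / PC aa C32:0
  kind: pair_ratio
  numerator: "lysoPC a C16:0"
  denominator: "PC aa C32:0"
- name: lysoPC a C18:1 / PC aa C36:2
  kind: pair_ratio
  numerator: "lysoPC a C18:1"
  denominator: "PC aa C36:2"
- name: lysoPC a C18:2 / PC aa C36:4
  kind: pair_ratio
  numerator: "lysoPC a C18:2"
  denominator: "PC aa C36:4"
- name: lysoPC a C18:0 / PC aa C36:0
  kind: pair_ratio
  numerator: "lysoPC a C18:0"
  denominator: "PC aa C36:0"
- name: PC aa C34:4 / PC aa C34:3
  kind: pair_ratio
  numerator: "PC aa C34:4"
  denominator: "PC aa C34:3"
- name: PC aa C36:4 / PC aa C36:5
  kind: pair_ratio
  numerator: "PC aa C36:4"
  denominator: "PC aa C36:5"
- name: PC aa C38:4 / PC aa C38:3
  kind: pair_ratio
  numerator: "PC aa C38:4"
  denominator: "PC aa C38:3"
- name: PC aa C32:1 / PC aa C32:0
  kind: pair_ratio
  numerator: "PC aa C32:1"
  denominator: "PC aa C32:0"
- name: PC aa C36:1 / PC aa C36:2
  kind: pair_ratio
  numerator: "PC aa C36:1"
  denominator: "PC aa C36:2"
- name: PC ae C36:2 / PC aa C36:2
  kind: pair_ratio
  numerator: "PC ae C36:2"
  denominator: "PC aa C36:2"
- name: PC ae C38:4 / PC aa C38:4
  kind: pair_ratio
  numerator: "PC ae C38:4"
  denominator: "PC aa C38:4"
- name: SM C16:0 / SM C16:1
  kind: pair_ratio
  numerator: "SM C16:0"
  denominator: "SM C16:1"
- name: SM C24:1 / SM C24:0
  kind: pair_ratio
  numerator: "SM C24:1"
  denominator: "SM C24:0"
- name: SM (OH) C22:1 / SM C22:3
  kind: pair_ratio
  numerator: "SM (OH) C22:1"
  denominator: "SM C22:3"
- name: SM (OH) C22:2 / SM C22:3
  kind: pair_ratio
  numerator: "SM (OH) C22:2"
  denominator: "SM C22:3"
- name: C2 / C0
  kind: pair_ratio
  numerator: "C2"
  denominator: "C0"
- name: C3 / C0
  kind: pair_ratio
  numerator: "C3"
  denominator: "C0"
- name: C4 / C0
  kind: pair_ratio
  numerator: "C4"
  denominator: "C0"
- name: C16 / C0
  kind: pair_ratio
  numerator: "C16"
  denominator: "C0"
- name: C5-DC / C5
  kind: pair_ratio
  numerator: "C5-DC"
  denominator: "C5"
- name: C8 / C10
  kind: pair_ratio
  numerator: "C8"
  denominator: "C10"
- name: C14:1 / C16
  kind: pair_ratio
  numerator: "C14:1"
  denominator: "C16"
- name: C18:1 / C18
  kind: pair_ratio
  numerator: "C18:1"
  denominator: "C18"
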