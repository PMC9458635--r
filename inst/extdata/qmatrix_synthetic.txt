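0.619970723 0.000000000 0.000000000 0.000000000 0.002692203 0.000000000 0.377337074 0.000000000
0.000000000 0.000000000 0.000000000 0.037957217 0.000000000 0.962042783 0.000000000 0.000000000
0.443511584 0.000000000 0.000000000 0.000000000 0.012336598 0.000000000 0.544151818 0.000000000
0.115505993 0.000000000 0.000000000 0.000000000 0.000000000 0.000000000 0.017804518 0.866689489
0.079524766 0.000000000 0.000000000 0.000000000 0.000000000 0.000000000 0.016387326 0.904087908
0.689793315 0.000000000 0.000000000 0.000000000 0.007089953 0.000000000 0.303116732 0.000000000
0.619796903 0.000000000 0.000000000 0.000000000 0.001337385 0.000000000 0.378865711 0.000000000
0.587221811 0.000000000 0.000000000 0.000000000 0.011357592 0.000000000 0.401420597 0.000000000
0.352573603 0.000000000 0.000000000 0.000000000 0.004784262 0.000000000 0.642642135 0.000000000
0.622534296 0.000000000 0.000000000 0.000000000 0.021195732 0.000000000 0.356269972 0.000000000
0.657873230 0.000000000 0.000000000 0.000000000 0.009390456 0.000000000 0.332736315 0.000000000
0.437061863 0.000000000 0.000000000 0.000000000 0.029870276 0.000000000 0.533067861 0.000000000
0.000000000 0.000000000 0.000000000 0.037858729 0.000000000 0.962141271 0.000000000 0.000000000
0.050862225 0.000000000 0.000000000 0.000000000 0.000000000 0.000000000 0.035620979 0.913516796
0.720993436 0.000000000 0.000000000 0.000933722 0.000000000 0.278072842 0.000000000 0.000000000
0.049270669 0.000000000 0.000000000 0.000000000 0.000000000 0.000000000 0.026590120 0.924139212
0.674256309 0.000000000 0.000000000 0.000000000 0.013545393 0.000000000 0.312198299 0.000000000
0.696818132 0.000000000 0.000000000 0.000000000 0.018789396 0.000000000 0.284392472 0.000000000
0.114485769 0.000000000 0.000000000 0.000000000 0.000000000 0.000000000 0.015691539 0.869822691
0.516498239 0.000000000 0.000000000 0.000000000 0.015310541 0.000000000 0.468191220 0.000000000
0.000000000 0.000000000 0.000000000 0.041265065 0.000000000 0.958734935 0.000000000 0.000000000
0.704314863 0.000000000 0.000000000 0.019322933 0.000000000 0.276362204 0.000000000 0.000000000
0.723225786 0.000000000 0.000000000 0.017334574 0.000000000 0.259439640 0.000000000 0.000000000
0.318073568 0.000000000 0.000000000 0.000000000 0.002350996 0.000000000 0.679575436 0.000000000
0.441748817 0.000000000 0.000000000 0.000000000 0.003342305 0.000000000 0.554908879 0.000000000
0.513433007 0.000000000 0.000000000 0.018209978 0.000000000 0.468357015 0.000000000 0.000000000
0.492264063 0.000000000 0.000000000 0.000000000 0.023780973 0.000000000 0.483954965 0.000000000
0.687004533 0.000000000 0.000000000 0.000000000 0.001475998 0.000000000 0.311519469 0.000000000
0.480000000 0.000000000 0.000000000 0.000000000 0.000000000 0.250000000 0.270000000 0.000000000
0.328149793 0.000000000 0.000000000 0.000000000 0.017610709 0.000000000 0.654239498 0.000000000
0.099629683 0.000000000 0.000000000 0.000000000 0.000000000 0.000000000 0.001924172 0.898446145
0.565987149 0.000000000 0.000000000 0.000000000 0.022436557 0.000000000 0.411576294 0.000000000
0.609497043 0.000000000 0.000000000 0.000000000 0.005640802 0.000000000 0.384862156 0.000000000
0.725385783 0.000000000 0.000000000 0.000000000 0.010455122 0.000000000 0.264159095 0.000000000
0.000000000 0.000000000 0.000000000 0.026499226 0.000000000 0.973500774 0.000000000 0.000000000
0.705544522 0.000000000 0.000000000 0.000000000 0.005390925 0.000000000 0.289064554 0.000000000
0.641498778 0.000000000 0.000000000 0.029301377 0.000000000 0.329199845 0.000000000 0.000000000
0.679230636 0.000000000 0.000000000 0.008112314 0.000000000 0.312657050 0.000000000 0.000000000
0.086288434 0.000000000 0.000000000 0.000000000 0.000000000 0.000000000 0.001276365 0.912435201
0.515252990 0.000000000 0.000000000 0.000000000 0.006646221 0.000000000 0.478100789 0.000000000
0.028273599 0.000000000 0.000000000 0.000000000 0.000000000 0.000000000 0.031951100 0.939775301
0.071510568 0.000000000 0.000000000 0.000000000 0.000000000 0.000000000 0.006981269 0.921508163
0.546907835 0.000000000 0.000000000 0.000000000 0.023525066 0.000000000 0.429567099 0.000000000
0.342972401 0.000000000 0.000000000 0.000000000 0.011236482 0.000000000 0.645791118 0.000000000
0.614867026 0.000000000 0.000000000 0.000000000 0.015402035 0.000000000 0.369730938 0.000000000
0.671209240 0.000000000 0.000000000 0.000000000 0.029474691 0.000000000 0.299316070 0.000000000
0.480888876 0.000000000 0.000000000 0.000000000 0.024208680 0.000000000 0.494902443 0.000000000
0.345398451 0.000000000 0.000000000 0.000000000 0.008433015 0.000000000 0.646168534 0.000000000
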