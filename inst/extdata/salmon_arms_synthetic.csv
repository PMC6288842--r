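arm,chrom,start,end,class
Ssa01p,Ssa01,0,55000000,AORe
Ssa01q,Ssa01,55000000,119000000,AORe
Ssa02p,Ssa02,0,42000000,LORe
Ssa02q,Ssa02,42000000,93000000,LORe
Ssa03p,Ssa03,0,48000000,mixed
Ssa03q,Ssa03,48000000,93000000,LORe
Ssa04p,Ssa04,0,39000000,LORe
Ssa04q,Ssa04,39000000,85000000,AORe
Ssa05p,Ssa05,0,37000000,mixed
Ssa05q,Ssa05,37000000,82000000,LORe
Ssa06p,Ssa06,0,41000000,LORe
Ssa06q,Ssa06,41000000,88000000,AORe
Ssa07p,Ssa07,0,28000000,AORe
Ssa07q,Ssa07,28000000,65000000,LORe
Ssa08p,Ssa08,0,12000000,AORe
Ssa08q,Ssa08,12000000,28000000,LORe
Ssa09p,Ssa09,0,40000000,AORe
Ssa09qa,Ssa09,40000000,90000000,AORe
Ssa09qb,Ssa09,90000000,142000000,mixed
Ssa10p,Ssa10,0,52000000,AORe
Ssa10q,Ssa10,52000000,116000000,AORe
Ssa11qa,Ssa11,0,48000000,LORe
Ssa11qb,Ssa11,48000000,93000000,AORe
Ssa12qa,Ssa12,0,49000000,LORe
Ssa12qb,Ssa12,49000000,92000000,AORe
Ssa13qa,Ssa13,0,53000000,mixed
Ssa13qb,Ssa13,53000000,107000000,AORe
Ssa14p,Ssa14,0,43000000,AORe
Ssa14q,Ssa14,43000000,95000000,AORe
Ssa15qa,Ssa15,0,55000000,AORe
Ssa15qb,Ssa15,55000000,108000000,mixed
Ssa16qa,Ssa16,0,46000000,AORe
Ssa16qb,Ssa16,46000000,87000000,LORe
Ssa17qa,Ssa17,0,32000000,LORe
Ssa17qb,Ssa17,32000000,64000000,LORe
Ssa18p,Ssa18,0,34000000,AORe
Ssa18q,Ssa18,34000000,72000000,AORe
Ssa19p,Ssa19,0,39000000,AORe
Ssa19q,Ssa19,39000000,84000000,AORe
Ssa20p,Ssa20,0,43000000,AORe
Ssa20q,Ssa20,43000000,88000000,AORe
Ssa21q,Ssa21,0,59000000,AORe
Ssa22q,Ssa22,0,64000000,AORe
Ssa23q,Ssa23,0,50000000,mixed
Ssa24q,Ssa24,0,49000000,AORe
Ssa25q,Ssa25,0,54000000,AORe
Ssa26q,Ssa26,0,49000000,LORe
Ssa27q,Ssa27,0,45000000,AORe
Ssa28q,Ssa28,0,41000000,AORe
Ssa29q,Ssa29,0,43000000,AORe
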