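#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord
# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target
#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------
protA                -             77 TOYDOM               -             28   5.5e-48  148.2   5.9   1   2   3.4e-26   5.1e-26   78.0   0.6     1    28     5    32     5    32 0.99 toy target one
protA                -             77 TOYDOM               -             28   5.5e-48  148.2   5.9   2   2   9.4e-25   1.4e-24   73.3   0.6     1    28    46    73    46    73 0.99 toy target one
protB                -             46 TOYDOM               -             28   2.2e-25   75.9   0.1   1   2      0.98       1.5   -3.5   0.3    17    18     9    10     7    11 0.68 toy target two
protB                -             46 TOYDOM               -             28   2.2e-25   75.9   0.1   2   2   1.5e-25   2.2e-25   75.9   0.1     1    28    12    39    12    39 0.99 toy target two
#
# Program:         hmmsearch
# Version:         3.4 (Aug 2023)
# Pipeline mode:   SEARCH
# Query file:      toy.hmm
# Target file:     targets.fa
# Option settings: hmmsearch --domtblout domtbl.txt toy.hmm targets.fa 
# Current dir:     /root/pkg/scratch
# Date:            Thu Sep 10 19:56:39 2026
# [ok]
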