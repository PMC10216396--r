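HEADER    SYNTHETIC TEST FIXTURE
ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  GLY A   1       2.000   0.000   0.000  1.00  0.00           C
ATOM      3  C   GLY A   1       0.000   2.000   0.000  1.00  0.00           C
ATOM      4  O   GLY A   1       2.000   2.000   0.000  1.00  0.00           O
ATOM      5  HA  GLY A   1       9.000   9.000   9.000  1.00  0.00           H
ATOM      6  N   ALA A   2       3.800   0.000   0.000  1.00  0.00           N
ATOM      7  CA AALA A   2       4.800   0.000   0.000  0.60  0.00           C
ATOM      8  CA BALA A   2       6.800   0.000   0.000  0.40  0.00           C
ATOM      9  N   SER A   3       7.600   0.000   0.000  1.00  0.00           N
HETATM   10  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O
END
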