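ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N  
ATOM      2  H   GLY A   1      -0.474  -0.840   0.000  1.00  0.00           H  
ATOM      3  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C  
ATOM      4  HA2 GLY A   1       1.822  -0.500   0.880  1.00  0.00           H  
ATOM      5  HA3 GLY A   1       1.822  -0.500  -0.880  1.00  0.00           H  
ATOM      6  C   GLY A   1       1.999   1.420   0.000  1.00  0.00           C  
ATOM      7  O   GLY A   1       3.221   1.536   0.120  1.00  0.00           O  
END   
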