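# Annotated example of the simplified AIMAll-style summary dialect read by
# read_aimall_sum(). Two sections with fixed headers; fields are
# whitespace-delimited; blank lines and lines starting with '#' are ignored.
# All energies are in hartree and are converted to kcal/mol on read;
# charges q(A) are in e.

[Atomic Properties]
Atom   q(A)
Li27   0.9463
C28   -0.8910
C29   -0.2101

# Unordered pairs, one per line; (A,B) and (B,A) are the same record.
[IQA Pairwise]
A      B      Vcl(A,B)     VXC(A,B)
Li27   C28    -0.144861    -0.025497
Li27   C29    -0.052113    -0.004782
C28    C29    -0.198440    -0.310925
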