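channel	synthetic_flat	synthetic_cpg	synthetic_guanine_adduct	synthetic_alkylating	synthetic_ageing
A[C>A]A	0.0104163500000002	0.00104134999999995	0.0037013	0.00500003999999998	0.01562496
A[C>A]C	0.01041667	0.00104167	0.10363636	0.005	0.015625
A[C>A]G	0.01041667	0.00104167	0.0037013	0.005	0.015625
A[C>A]T	0.01041667	0.00104167	0.03146104	0.005	0.015625
C[C>A]A	0.01041667	0.00104167	0.0037013	0.005	0.015625
C[C>A]C	0.01041667	0.00104167	0.10363636	0.005	0.015625
C[C>A]G	0.01041667	0.00104167	0.0037013	0.005	0.015625
C[C>A]T	0.01041667	0.00104167	0.03146104	0.005	0.015625
G[C>A]A	0.01041667	0.00104167	0.0037013	0.005	0.015625
G[C>A]C	0.01041667	0.00104167	0.10363636	0.005	0.015625
G[C>A]G	0.01041667	0.00104167	0.0037013	0.005	0.015625
G[C>A]T	0.01041667	0.00104167	0.03146104	0.005	0.015625
T[C>A]A	0.01041667	0.00104167	0.0037013	0.005	0.015625
T[C>A]C	0.01041667	0.00104167	0.10363636	0.005	0.015625
T[C>A]G	0.01041667	0.00104167	0.0037013	0.005	0.015625
T[C>A]T	0.01041667	0.00104167	0.03146104	0.005	0.015625
A[C>G]A	0.01041667	0.00104167	0.00375	0.003125	0.005
A[C>G]C	0.01041667	0.00104167	0.00375	0.003125	0.005
A[C>G]G	0.01041667	0.00104167	0.00375	0.003125	0.005
A[C>G]T	0.01041667	0.00104167	0.00375	0.003125	0.005
C[C>G]A	0.01041667	0.00104167	0.00375	0.003125	0.005
C[C>G]C	0.01041667	0.00104167	0.00375	0.003125	0.005
C[C>G]G	0.01041667	0.00104167	0.00375	0.003125	0.005
C[C>G]T	0.01041667	0.00104167	0.00375	0.003125	0.005
G[C>G]A	0.01041667	0.00104167	0.00375	0.003125	0.005
G[C>G]C	0.01041667	0.00104167	0.00375	0.003125	0.005
G[C>G]G	0.01041667	0.00104167	0.00375	0.003125	0.005
G[C>G]T	0.01041667	0.00104167	0.00375	0.003125	0.005
T[C>G]A	0.01041667	0.00104167	0.00375	0.003125	0.005
T[C>G]C	0.01041667	0.00104167	0.00375	0.003125	0.005
T[C>G]G	0.01041667	0.00104167	0.00375	0.003125	0.005
T[C>G]T	0.01041667	0.00104167	0.00375	0.003125	0.005
A[C>T]A	0.01041667	0.00104167	0.00625	0.01875	0.00666667
A[C>T]C	0.01041667	0.00104167	0.00625	0.01875	0.00666667
A[C>T]G	0.01041667	0.22604167	0.00625	0.01875	0.08
A[C>T]T	0.01041667	0.00104167	0.00625	0.01875	0.00666667
C[C>T]A	0.01041667	0.00104167	0.00625	0.01875	0.00666667
C[C>T]C	0.01041667	0.00104167	0.00625	0.01875	0.00666667
C[C>T]G	0.01041667	0.22604167	0.00625	0.01875	0.08
C[C>T]T	0.01041667	0.00104167	0.00625	0.01875	0.00666667
G[C>T]A	0.01041667	0.00104167	0.00625	0.01875	0.00666667
G[C>T]C	0.01041667	0.00104167	0.00625	0.01875	0.00666667
G[C>T]G	0.01041667	0.22604167	0.00625	0.01875	0.08
G[C>T]T	0.01041667	0.00104167	0.00625	0.01875	0.00666667
T[C>T]A	0.01041667	0.00104167	0.00625	0.01875	0.00666667
T[C>T]C	0.01041667	0.00104167	0.00625	0.01875	0.00666667
T[C>T]G	0.01041667	0.22604167	0.00625	0.01875	0.08
T[C>T]T	0.01041667	0.00104167	0.00625	0.01875	0.00666667
A[T>A]A	0.01041667	0.00104167	0.002	0.00448718	0.004375
A[T>A]C	0.01041667	0.00104167	0.024	0.00448718	0.004375
A[T>A]G	0.01041667	0.00104167	0.002	0.00448718	0.004375
A[T>A]T	0.01041667	0.00104167	0.002	0.04487179	0.004375
C[T>A]A	0.01041667	0.00104167	0.002	0.00897436	0.004375
C[T>A]C	0.01041667	0.00104167	0.024	0.00897436	0.004375
C[T>A]G	0.01041667	0.00104167	0.002	0.00897436	0.004375
C[T>A]T	0.01041667	0.00104167	0.002	0.08974359	0.004375
G[T>A]A	0.01041667	0.00104167	0.002	0.00448718	0.004375
G[T>A]C	0.01041667	0.00104167	0.024	0.00448718	0.004375
G[T>A]G	0.01041667	0.00104167	0.002	0.00448718	0.004375
G[T>A]T	0.01041667	0.00104167	0.002	0.04487179	0.004375
T[T>A]A	0.01041667	0.00104167	0.002	0.00897436	0.004375
T[T>A]C	0.01041667	0.00104167	0.024	0.00897436	0.004375
T[T>A]G	0.01041667	0.00104167	0.002	0.00897436	0.004375
T[T>A]T	0.01041667	0.00104167	0.002	0.08974359	0.004375
A[T>C]A	0.01041667	0.00104167	0.005625	0.00428571	0.008125
A[T>C]C	0.01041667	0.00104167	0.005625	0.00428571	0.008125
A[T>C]G	0.01041667	0.00104167	0.005625	0.00428571	0.008125
A[T>C]T	0.01041667	0.00104167	0.005625	0.01714286	0.008125
C[T>C]A	0.01041667	0.00104167	0.005625	0.00428571	0.008125
C[T>C]C	0.01041667	0.00104167	0.005625	0.00428571	0.008125
C[T>C]G	0.01041667	0.00104167	0.005625	0.00428571	0.008125
C[T>C]T	0.01041667	0.00104167	0.005625	0.01714286	0.008125
G[T>C]A	0.01041667	0.00104167	0.005625	0.00428571	0.008125
G[T>C]C	0.01041667	0.00104167	0.005625	0.00428571	0.008125
G[T>C]G	0.01041667	0.00104167	0.005625	0.00428571	0.008125
G[T>C]T	0.01041667	0.00104167	0.005625	0.01714286	0.008125
T[T>C]A	0.01041667	0.00104167	0.005625	0.00428571	0.008125
T[T>C]C	0.01041667	0.00104167	0.005625	0.00428571	0.008125
T[T>C]G	0.01041667	0.00104167	0.005625	0.00428571	0.008125
T[T>C]T	0.01041667	0.00104167	0.005625	0.01714286	0.008125
A[T>G]A	0.01041667	0.00104167	0.00375	0.00357143	0.004375
A[T>G]C	0.01041667	0.00104167	0.00375	0.00357143	0.004375
A[T>G]G	0.01041667	0.00104167	0.00375	0.00357143	0.004375
A[T>G]T	0.01041667	0.00104167	0.00375	0.01428571	0.004375
C[T>G]A	0.01041667	0.00104167	0.00375	0.00357143	0.004375
C[T>G]C	0.01041667	0.00104167	0.00375	0.00357143	0.004375
C[T>G]G	0.01041667	0.00104167	0.00375	0.00357143	0.004375
C[T>G]T	0.01041667	0.00104167	0.00375	0.01428571	0.004375
G[T>G]A	0.01041667	0.00104167	0.00375	0.00357143	0.004375
G[T>G]C	0.01041667	0.00104167	0.00375	0.00357143	0.004375
G[T>G]G	0.01041667	0.00104167	0.00375	0.00357143	0.004375
G[T>G]T	0.01041667	0.00104167	0.00375	0.01428571	0.004375
T[T>G]A	0.01041667	0.00104167	0.00375	0.00357143	0.004375
T[T>G]C	0.01041667	0.00104167	0.00375	0.00357143	0.004375
T[T>G]G	0.01041667	0.00104167	0.00375	0.00357143	0.004375
T[T>G]T	0.01041667	0.00104167	0.00375	0.01428571	0.004375
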