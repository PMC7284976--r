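community	group	fraction
c1	RT1	0.90
c1	RT2/6	0.04
c1	RT3	0.03
c1	RT4/5	0.02
c1	RT8	0.01
c2	RT1	0.70
c2	RT2/6	0.10
c2	RT3	0.10
c2	RT4/5	0.05
c2	RT8	0.05
c3	RT2/6	0.80
c3	RT1	0.10
c3	RT3	0.05
c3	RT4/5	0.03
c3	RT8	0.02
c4	RT2/6	0.55
c4	RT1	0.20
c4	RT3	0.15
c4	RT4/5	0.05
c4	RT8	0.05
c5	RT1	0.50
c5	RT4/5	0.25
c5	RT3	0.15
c5	RT2/6	0.05
c5	RT8	0.05
c6	RT1	0.60
c6	RT1/IB-3	0.15
c6	RT2/6	0.10
c6	RT3	0.10
c6	RT8	0.05
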