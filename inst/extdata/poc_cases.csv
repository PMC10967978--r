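case,real_x,real_y,obt_x,obt_y
1,221.5,256.8,216.8,256.0
2,213.7,184.0,227.8,197.3
3,216.8,140.0,218.4,143.2
4,173.2,264.6,177.7,253.6
5,180.8,201.2,172.2,199.6
6,176.1,137.1,180.8,143.2
7,140.9,259.1,136.1,261.4
8,137.0,185.5,133.1,180.8
9,140.1,135.9,136.2,134.6
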