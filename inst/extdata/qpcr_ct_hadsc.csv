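gene,cell_line,condition,run,tech_rep,ct
ALAS1,A,Hx,1,1,27.2
ALAS1,A,Nx,1,1,25.0
RRP1,A,Hx,1,1,29.1
RRP1,A,Hx,1,2,29.7
RRP1,A,Hx,1,3,29.9
RRP1,A,Nx,1,1,29.2
RRP1,A,Nx,1,2,29.6
RRP1,A,Nx,1,3,29.6
18S,A,Hx,1,1,21.9
18S,A,Hx,1,2,21.7
18S,A,Hx,1,3,21.5
18S,A,Nx,1,1,20.3
18S,A,Nx,1,2,20.1
18S,A,Nx,1,3,20.2
PGK1,A,Hx,1,1,21.5
PGK1,A,Hx,1,2,21.5
PGK1,A,Hx,1,3,21.7
PGK1,A,Nx,1,1,25.4
PGK1,A,Nx,1,2,25.4
PGK1,A,Nx,1,3,25.6
GUSB,A,Hx,1,1,27.8
GUSB,A,Hx,1,2,28.0
GUSB,A,Nx,1,1,24.9
GUSB,A,Nx,1,2,25.1
ALAS1,A,Hx,2,1,29.6
ALAS1,A,Hx,2,2,29.5
ALAS1,A,Hx,2,3,29.9
ALAS1,A,Nx,2,1,26.3
ALAS1,A,Nx,2,2,26.1
ALAS1,A,Nx,2,3,26.2
RRP1,A,Hx,2,1,29.8
RRP1,A,Hx,2,2,29.6
RRP1,A,Hx,2,3,29.5
RRP1,A,Nx,2,1,30.5
RRP1,A,Nx,2,2,30.4
RRP1,A,Nx,2,3,30.5
GUSB,A,Hx,2,1,>35
GUSB,A,Hx,2,2,>35
GUSB,A,Hx,2,3,>35
GUSB,A,Nx,2,1,27.5
GUSB,A,Nx,2,2,27.3
GUSB,A,Nx,2,3,27.3
ALAS1,B,Hx,1,1,24.9
ALAS1,B,Nx,1,1,23.9
RRP1,B,Hx,1,1,25.6
RRP1,B,Hx,1,2,25.6
RRP1,B,Hx,1,3,25.8
RRP1,B,Nx,1,1,25.7
RRP1,B,Nx,1,2,25.7
RRP1,B,Nx,1,3,26.1
18S,B,Hx,1,1,18.7
18S,B,Hx,1,2,18.6
18S,B,Hx,1,3,18.8
18S,B,Nx,1,1,20.7
18S,B,Nx,1,2,20.6
18S,B,Nx,1,3,20.5
PGK1,B,Hx,1,1,20.1
PGK1,B,Hx,1,2,20.1
PGK1,B,Hx,1,3,20.1
PGK1,B,Nx,1,1,22.0
PGK1,B,Nx,1,2,22.0
PGK1,B,Nx,1,3,21.9
GUSB,B,Hx,1,1,25.0
GUSB,B,Hx,1,2,25.0
GUSB,B,Nx,1,1,23.9
GUSB,B,Nx,1,2,24.0
ALAS1,B,Hx,2,1,29.2
ALAS1,B,Hx,2,2,28.9
ALAS1,B,Hx,2,3,29.1
ALAS1,B,Nx,2,1,28.4
ALAS1,B,Nx,2,2,28.1
ALAS1,B,Nx,2,3,28.0
RRP1,B,Hx,2,1,30.8
RRP1,B,Hx,2,2,30.5
RRP1,B,Hx,2,3,30.8
RRP1,B,Nx,2,1,29.8
RRP1,B,Nx,2,2,29.7
RRP1,B,Nx,2,3,29.7
GUSB,B,Hx,2,1,>35
GUSB,B,Hx,2,2,>35
GUSB,B,Hx,2,3,>35
GUSB,B,Nx,2,1,>35
GUSB,B,Nx,2,2,>35
GUSB,B,Nx,2,3,>35
ALAS1,C,Hx,1,1,26.5
ALAS1,C,Hx,1,2,26.3
ALAS1,C,Hx,1,3,26.4
ALAS1,C,Nx,1,1,25.9
ALAS1,C,Nx,1,2,25.8
ALAS1,C,Nx,1,3,25.7
RRP1,C,Hx,1,1,31.3
RRP1,C,Hx,1,2,31.1
RRP1,C,Hx,1,3,31.1
RRP1,C,Nx,1,1,31.5
RRP1,C,Nx,1,2,31.2
RRP1,C,Nx,1,3,31.1
18S,C,Hx,1,1,19.5
18S,C,Hx,1,2,19.7
18S,C,Hx,1,3,19.6
18S,C,Nx,1,1,19.4
18S,C,Nx,1,2,19.3
18S,C,Nx,1,3,19.3
PGK1,C,Hx,1,1,22.4
PGK1,C,Hx,1,2,22.4
PGK1,C,Hx,1,3,22.4
PGK1,C,Nx,1,1,25.7
PGK1,C,Nx,1,2,25.7
PGK1,C,Nx,1,3,25.9
GUSB,C,Hx,1,1,27.1
GUSB,C,Hx,1,2,27.1
GUSB,C,Hx,1,3,27.2
GUSB,C,Nx,1,1,26.3
GUSB,C,Nx,1,2,26.3
GUSB,C,Nx,1,3,26.2
ALAS1,C,Hx,2,1,29.7
ALAS1,C,Hx,2,2,29.5
ALAS1,C,Hx,2,3,29.6
ALAS1,C,Nx,2,1,29.1
ALAS1,C,Nx,2,2,29.2
ALAS1,C,Nx,2,3,29.0
RRP1,C,Hx,2,1,29.9
RRP1,C,Hx,2,2,29.7
RRP1,C,Hx,2,3,30.0
RRP1,C,Nx,2,1,29.5
RRP1,C,Nx,2,2,29.3
RRP1,C,Nx,2,3,29.2
18S,C,Hx,2,1,20.9
18S,C,Hx,2,2,20.2
18S,C,Hx,2,3,20.3
18S,C,Nx,2,1,20.9
18S,C,Nx,2,2,20.6
18S,C,Nx,2,3,20.4
PGK1,C,Hx,2,1,22.2
PGK1,C,Hx,2,2,22.4
PGK1,C,Hx,2,3,22.4
PGK1,C,Nx,2,1,25.5
PGK1,C,Nx,2,2,25.7
PGK1,C,Nx,2,3,25.7
GUSB,C,Hx,2,1,31.8
GUSB,C,Hx,2,2,31.2
GUSB,C,Hx,2,3,32.3
GUSB,C,Nx,2,1,33.7
GUSB,C,Nx,2,2,34.2
GUSB,C,Nx,2,3,>35
ALAS1,D,Hx,1,1,31.6
ALAS1,D,Hx,1,2,31.8
ALAS1,D,Hx,1,3,31.8
ALAS1,D,Nx,1,1,29.0
ALAS1,D,Nx,1,2,28.9
ALAS1,D,Nx,1,3,29.0
RRP1,D,Hx,1,1,33.6
RRP1,D,Hx,1,2,33.8
RRP1,D,Hx,1,3,33.5
RRP1,D,Nx,1,1,32.5
RRP1,D,Nx,1,2,32.6
RRP1,D,Nx,1,3,32.3
18S,D,Hx,1,1,26.4
18S,D,Hx,1,2,26.3
18S,D,Hx,1,3,26.5
18S,D,Nx,1,1,25.2
18S,D,Nx,1,2,25.1
18S,D,Nx,1,3,25.3
PGK1,D,Hx,1,1,25.5
PGK1,D,Hx,1,2,25.5
PGK1,D,Hx,1,3,25.5
PGK1,D,Nx,1,1,29.7
PGK1,D,Nx,1,2,29.8
PGK1,D,Nx,1,3,29.4
GUSB,D,Hx,1,1,>35
GUSB,D,Hx,1,2,>35
GUSB,D,Hx,1,3,>35
GUSB,D,Nx,1,1,30.7
GUSB,D,Nx,1,2,31.0
GUSB,D,Nx,1,3,30.8
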