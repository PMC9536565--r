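letter,line_vertical,line_horizontal,line_slant_right,line_slant_left,curve_open_right,curve_open_left,curve_open_bottom,curve_open_top,intersections_2way,intersections_3way,intersections_4way,terminations_right,terminations_left,terminations_bottom,terminations_top,diacritics,symmetry,closed_space
a,1,0,0,0,0,1,0,0,0,2,0,1,0,1,1,0,0,1
b,1,0,0,0,0,0,0,0,0,2,0,0,0,0,1,0,0,1
c,0,0,0,0,1,0,0,0,0,0,0,2,0,0,0,0,1,0
d,1,0,0,0,0,0,0,0,0,2,0,0,0,0,1,0,0,1
e,0,1,0,0,1,0,0,0,0,2,0,1,0,0,0,0,0,1
f,1,1,0,0,0,0,0,1,0,1,1,1,1,1,0,0,0,0
g,1,0,0,0,0,0,0,1,0,2,0,0,1,0,1,0,0,1
h,1,0,0,0,0,0,1,0,0,2,0,0,0,2,1,0,1,0
i,1,0,0,0,0,0,0,0,0,0,0,0,0,1,1,1,1,0
j,1,0,0,0,0,0,0,1,0,0,0,0,1,0,1,1,0,0
k,1,0,1,1,0,0,0,0,0,2,0,1,0,2,2,0,0,0
l,1,0,0,0,0,0,0,0,0,0,0,0,0,1,1,0,1,0
m,3,0,0,0,0,0,2,0,0,2,0,0,0,3,1,0,1,0
n,2,0,0,0,0,0,1,0,0,2,0,0,0,2,1,0,1,0
o,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,1
p,1,0,0,0,0,0,0,0,0,2,0,0,0,1,1,0,0,1
q,1,0,0,0,0,0,0,0,0,2,0,0,0,1,1,0,0,1
r,1,0,0,0,0,0,1,0,0,1,0,1,0,1,1,0,0,0
s,0,0,0,0,1,1,0,0,0,0,0,1,1,0,0,0,0,0
t,1,1,0,0,0,0,0,1,0,0,1,1,1,1,1,0,0,0
u,2,0,0,0,0,0,0,1,0,1,0,0,0,1,2,0,1,0
v,0,0,1,1,0,0,0,1,0,1,0,0,0,0,2,0,1,0
w,0,0,2,2,0,0,0,2,0,2,0,0,0,0,2,0,1,0
x,0,0,1,1,0,0,0,0,0,0,1,0,0,2,2,0,1,0
y,0,0,1,1,0,0,0,1,0,1,0,0,0,1,2,0,0,0
z,0,2,0,1,0,0,0,0,0,2,0,1,1,0,0,0,0,0
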