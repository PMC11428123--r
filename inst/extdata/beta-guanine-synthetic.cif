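# SYNTHETIC approximation of the beta-guanine packing motif
# (monoclinic P21/c, Z=4; pi-stacking along a, triple-H-bond
# chain along b, H-bond dimer link in the bc plane).
# Idealized coordinates generated by xtalgrow::synth_beta_guanine();
# NOT the published experimental structure.
data_beta_guanine_synthetic
_cell_length_a    3.550000
_cell_length_b    8.800000
_cell_length_c    16.500000
_cell_angle_alpha 90.000000
_cell_angle_beta  96.000000
_cell_angle_gamma 90.000000
loop_
_symmetry_equiv_pos_as_xyz
'x,y,z'
'-x,y+1/2,-z+1/2'
'-x,-y,-z'
'x,-y+1/2,z+1/2'
loop_
_atom_site_label
_atom_site_type_symbol
_atom_site_fract_x
_atom_site_fract_y
_atom_site_fract_z
_atom_site_occupancy
N1 N 0.14324657 0.06463054 0.17040886 1.0
C2 C -0.08502757 0.03869648 0.09804644 1.0
N3 N -0.23206949 0.16066572 0.05143447 1.0
C4 C -0.15083725 0.30856902 0.07718491 1.0
C5 C 0.07743689 0.33450308 0.14954733 1.0
C6 C 0.22447881 0.21253384 0.19615931 1.0
N7 N 0.11184187 0.49070220 0.16045364 1.0
C8 C -0.09516883 0.56130450 0.09483168 1.0
N9 N -0.25751346 0.44874001 0.04336878 1.0
O10 O 0.42811905 0.23566926 0.26071283 1.0
N11 N -0.16450659 -0.10601466 0.07285176 1.0
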