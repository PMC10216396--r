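data_FIX
#
loop_
_atom_site.group_PDB
_atom_site.id
_atom_site.type_symbol
_atom_site.label_atom_id
_atom_site.label_alt_id
_atom_site.label_comp_id
_atom_site.label_asym_id
_atom_site.label_entity_id
_atom_site.label_seq_id
_atom_site.pdbx_PDB_ins_code
_atom_site.Cartn_x
_atom_site.Cartn_y
_atom_site.Cartn_z
_atom_site.occupancy
_atom_site.B_iso_or_equiv
_atom_site.pdbx_formal_charge
_atom_site.auth_seq_id
_atom_site.auth_comp_id
_atom_site.auth_asym_id
_atom_site.auth_atom_id
_atom_site.pdbx_PDB_model_num
ATOM 1  N N  . GLY A 1 1 ? 0.000 0.000 0.000 1.00 0.00 ? 1   GLY A N  1
ATOM 2  C CA . GLY A 1 1 ? 2.000 0.000 0.000 1.00 0.00 ? 1   GLY A CA 1
ATOM 3  C C  . GLY A 1 1 ? 0.000 2.000 0.000 1.00 0.00 ? 1   GLY A C  1
ATOM 4  O O  . GLY A 1 1 ? 2.000 2.000 0.000 1.00 0.00 ? 1   GLY A O  1
ATOM 5  N N  . ALA A 1 2 ? 3.800 0.000 0.000 1.00 0.00 ? 2   ALA A N  1
ATOM 6  C CA A ALA A 1 2 ? 4.800 0.000 0.000 0.60 0.00 ? 2   ALA A CA 1
ATOM 7  C CA B ALA A 1 2 ? 6.800 0.000 0.000 0.40 0.00 ? 2   ALA A CA 1
ATOM 8  N N  . SER A 1 3 ? 7.600 0.000 0.000 1.00 0.00 ? 3   SER A N  1
HETATM 9 O O  . HOH A 2 . ? 9.000 9.000 9.000 1.00 0.00 ? 101 HOH A O  1
#
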