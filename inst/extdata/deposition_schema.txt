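# minidep deposition validation dictionary (core + experiment/declaration categories)
version 1.0

category entity key=id
item entity.id type=int mandatory=yes
item entity.type type=enum mandatory=yes enum="polymer|non-polymer|water"
item entity.pdbx_description type=text
item entity.pdbx_number_of_molecules type=int

category entity_poly key=entity_id
item entity_poly.entity_id type=int mandatory=yes parent=entity.id
item entity_poly.type type=enum enum="polypeptide(L)|polyribonucleotide|polydeoxyribonucleotide"
item entity_poly.pdbx_seq_one_letter_code type=text mandatory=yes
item entity_poly.pdbx_strand_id type=text mandatory=yes

category entity_src_gen key=entity_id
item entity_src_gen.entity_id type=int mandatory=yes parent=entity.id
item entity_src_gen.pdbx_gene_src_scientific_name type=text
item entity_src_gen.pdbx_gene_src_ncbi_taxonomy_id type=int
item entity_src_gen.pdbx_host_org_scientific_name type=text
item entity_src_gen.pdbx_host_org_ncbi_taxonomy_id type=int
item entity_src_gen.pdbx_host_org_vector_type type=enum enum="plasmid|virus|cosmid|baculovirus"
item entity_src_gen.plasmid_name type=text

category atom_site key=id
item atom_site.id type=int mandatory=yes
item atom_site.auth_asym_id type=text mandatory=yes
item atom_site.auth_seq_id type=int mandatory=yes
item atom_site.label_comp_id type=text mandatory=yes
item atom_site.label_atom_id type=text mandatory=yes
item atom_site.type_symbol type=text mandatory=yes
item atom_site.label_alt_id type=text
item atom_site.Cartn_x type=float mandatory=yes hard=-1000:1000
item atom_site.Cartn_y type=float mandatory=yes hard=-1000:1000
item atom_site.Cartn_z type=float mandatory=yes hard=-1000:1000
item atom_site.occupancy type=float mandatory=yes hard=0:1
item atom_site.B_iso_or_equiv type=float mandatory=yes hard=0:1000

category cell
item cell.length_a type=float mandatory=yes hard=1:1000
item cell.length_b type=float mandatory=yes hard=1:1000
item cell.length_c type=float mandatory=yes hard=1:1000
item cell.angle_alpha type=float hard=10:170
item cell.angle_beta type=float hard=10:170
item cell.angle_gamma type=float hard=10:170

category symmetry
item symmetry.space_group_name_H-M type=text mandatory=yes

category reflns
item reflns.pdbx_Rmerge_I_obs type=float hard=0:1000 soft=0.01:0.2
item reflns.pdbx_wavelength type=float hard=0.1:10 soft=0.5:3
item reflns.pdbx_R_free_flag_present type=enum enum="Y|N"
item reflns.pdbx_completeness type=float hard=0:100
item reflns.d_resolution_high type=float hard=0.1:100

category exptl
item exptl.method type=enum mandatory=yes enum="X-RAY DIFFRACTION|ELECTRON MICROSCOPY|SOLUTION NMR"

category diffrn_radiation_wavelength key=id
item diffrn_radiation_wavelength.id type=int mandatory=yes
item diffrn_radiation_wavelength.wavelength type=float hard=0.1:10

category pdbx_struct_oper_list key=id
item pdbx_struct_oper_list.id type=text mandatory=yes
item pdbx_struct_oper_list.matrix[1][1] type=float mandatory=yes
item pdbx_struct_oper_list.matrix[1][2] type=float mandatory=yes
item pdbx_struct_oper_list.matrix[1][3] type=float mandatory=yes
item pdbx_struct_oper_list.matrix[2][1] type=float mandatory=yes
item pdbx_struct_oper_list.matrix[2][2] type=float mandatory=yes
item pdbx_struct_oper_list.matrix[2][3] type=float mandatory=yes
item pdbx_struct_oper_list.matrix[3][1] type=float mandatory=yes
item pdbx_struct_oper_list.matrix[3][2] type=float mandatory=yes
item pdbx_struct_oper_list.matrix[3][3] type=float mandatory=yes
item pdbx_struct_oper_list.vector[1] type=float mandatory=yes
item pdbx_struct_oper_list.vector[2] type=float mandatory=yes
item pdbx_struct_oper_list.vector[3] type=float mandatory=yes

category minidep_declaration
item minidep_declaration.kind type=text mandatory=yes
item minidep_declaration.value type=text mandatory=yes
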