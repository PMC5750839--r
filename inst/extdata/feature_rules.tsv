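# shapefish pharmacophore feature rules
# version: 1
#
# One rule per line: <feature_type> TAB <DETECTOR_NAME>.
# feature_type is one of: donor acceptor cation anion hydrophobe aromatic.
# Detectors are named structural patterns evaluated on the molecular graph
# (ionizable groups are typed for physiological pH ~7.4, no pKa model):
#   NH_OH           N or O carrying at least one (implicit or explicit) H
#   N_O_LONEPAIR    any N or O (lone-pair bearer)
#   ALIPHATIC_AMINE non-aromatic N, single bonds, C-only neighbours, no
#                   adjacent carbonyl (protonated at pH 7.4)
#   CARBOXYLATE     C(=O)O group, feature centred between the oxygens
#                   (deprotonated at pH 7.4)
#   AROMATIC_RING   centroid of an aromatic ring (all-aromatic bond orders
#                   or alternating Kekule single/double carbocycle)
#   CARBON_GROUP    centroid of each connected group of >= 3 carbons with
#                   no polar neighbour
# Removing a line disables that feature type; the version string above is
# carried into feature models and run sidecars.
donor	NH_OH
acceptor	N_O_LONEPAIR
cation	ALIPHATIC_AMINE
anion	CARBOXYLATE
aromatic	AROMATIC_RING
hydrophobe	CARBON_GROUP
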