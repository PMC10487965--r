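symbol	is_mito_encoded	is_mito_mrna	is_mang	is_tf	slc_family	chromosome
mt-Nd1	TRUE	TRUE	FALSE	FALSE		chrM
mt-Nd2	TRUE	TRUE	FALSE	FALSE		chrM
mt-Co1	TRUE	TRUE	FALSE	FALSE		chrM
mt-Co2	TRUE	TRUE	FALSE	FALSE		chrM
mt-Atp8	TRUE	TRUE	FALSE	FALSE		chrM
mt-Atp6	TRUE	TRUE	FALSE	FALSE		chrM
mt-Co3	TRUE	TRUE	FALSE	FALSE		chrM
mt-Nd3	TRUE	TRUE	FALSE	FALSE		chrM
mt-Nd4l	TRUE	TRUE	FALSE	FALSE		chrM
mt-Nd4	TRUE	TRUE	FALSE	FALSE		chrM
mt-Nd5	TRUE	TRUE	FALSE	FALSE		chrM
mt-Nd6	TRUE	TRUE	FALSE	FALSE		chrM
mt-Cytb	TRUE	TRUE	FALSE	FALSE		chrM
mt-Rnr1	TRUE	FALSE	FALSE	FALSE		chrM
mt-Rnr2	TRUE	FALSE	FALSE	FALSE		chrM
mt-Tf	TRUE	FALSE	FALSE	FALSE		chrM
mt-Tv	TRUE	FALSE	FALSE	FALSE		chrM
mt-Tl1	TRUE	FALSE	FALSE	FALSE		chrM
mt-Ti	TRUE	FALSE	FALSE	FALSE		chrM
mt-Tq	TRUE	FALSE	FALSE	FALSE		chrM
mt-Tm	TRUE	FALSE	FALSE	FALSE		chrM
mt-Tw	TRUE	FALSE	FALSE	FALSE		chrM
mt-Ta	TRUE	FALSE	FALSE	FALSE		chrM
mt-Tn	TRUE	FALSE	FALSE	FALSE		chrM
mt-Tc	TRUE	FALSE	FALSE	FALSE		chrM
mt-Ty	TRUE	FALSE	FALSE	FALSE		chrM
mt-Ts1	TRUE	FALSE	FALSE	FALSE		chrM
mt-Td	TRUE	FALSE	FALSE	FALSE		chrM
mt-Tk	TRUE	FALSE	FALSE	FALSE		chrM
mt-Tg	TRUE	FALSE	FALSE	FALSE		chrM
mt-Tr	TRUE	FALSE	FALSE	FALSE		chrM
mt-Th	TRUE	FALSE	FALSE	FALSE		chrM
mt-Ts2	TRUE	FALSE	FALSE	FALSE		chrM
mt-Tl2	TRUE	FALSE	FALSE	FALSE		chrM
mt-Te	TRUE	FALSE	FALSE	FALSE		chrM
mt-Tt	TRUE	FALSE	FALSE	FALSE		chrM
mt-Tp	TRUE	FALSE	FALSE	FALSE		chrM
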