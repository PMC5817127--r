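(Liriodendron_tulipifera,(((Celastrus_scandens,((Cercis_canadensis,Robinia_pseudoacacia),(Carya,(Juglans_nigra,Juglans_cinerea)))),(Dirca_palustris,Ptelea_trifoliata)),((Sideroxylon_lycioides,Sideroxylon_lanuginosum),(Viburnum_cassinoides,(Viburnum_lentago,(Viburnum_prunifolium,Viburnum_rufidulum))))));
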