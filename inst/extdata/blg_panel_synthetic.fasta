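>SYNBLG_BOS|Bos|lineage:Mammalia>Pecora>Bovidae>Bovinae>Bos
LITTATMKGLDIQKVAGTWYSLAMAASDISLLDAQSAPLRTYTEELKPTPEGDLEILLAK
WEGGECAQKKIIAEKTKIPAVFKIDALNENKVLVVDTDYKKYVLFCMENSAEPEQSLACQ
CLTRTPEVDDAALEKFDKALKAVPMHIRVSFNPTQLEEQCHI
>SYNBLG_BUBALUS|Bubalus|lineage:Mammalia>Pecora>Bovidae>Bovinae>Bubalus
LITTQTMKGLGIQKVAGTWYSLSMAASDVSLLDAQSAPLRVYTEELKPTPEGDLEILLQK
WEGGACAQKKIIAEKTKIPAVFKIDALNENKVLVLDTDYKKYVLFCMENSAEPEQSLACQ
CLTRTPEVDDEALEKFGKALKAVPMHIRLSFNPTALEEQCHI
>SYNBLG_OVIS|Ovis|lineage:Mammalia>Pecora>Bovidae>Caprinae>Ovis
LIVTQTMKGLDIAKVAGTWYSLAMAASGISVLDAQSAPLRVYVEELKPVPEGDLEILLQK
WENGECSAKKIIAEKTKIPAVFKIGALGENKVLVLDTDYKKYVLFCMANSAEPEQSLACQ
CLVRTPETDDEALEKFDKSLKALPMHIRLSFNPTQLAEQCHI
>SYNBLG_CAPRA|Capra|lineage:Mammalia>Pecora>Bovidae>Caprinae>Capra
LIVTQTMKGLDIQKVSGTWYSLAMAASGISLLDSQSAPLRVYVEELKPTPEADLEILLQK
WENGECAAKKIIAEKTKIPAVFKIDALAENKVLVLDTDYKKYLLFCMANSAEPEQSLACQ
CLVRTPETDDEALEKFDKALKSLPMHIRLSFNPTQLEEQCHI
>SYNBLG_RANGIFER|Rangifer|lineage:Mammalia>Pecora>Cervidae>Rangifer
LIVTQTMKALDIQKVAGTWYSLSMAASDISLLDAQSSPLRVYVEELKPTPAGDLEILLQK
WENGACAQKKIIAEKTKIPAVFKIDALNENKVVVLDTDYKKYLLFCVENSAEPEQSLACQ
CLVRTPEVDDEALEKFDKALKALPMHIRVSFNPTQLEEQCHI
>SYNBLG_EQUUS|Equus|lineage:Mammalia>Equidae>Equus
LIVTQTVKGLDIQKVAGTWYALAMAASGISLLDAASAPLRVFVEELKPVPEGDLEVLLQK
WEGGECAQKKIIAEKTKIPAVFKVDALNENKVLVLDTGYKKYLLYCMENSAAPEQSLACQ
CLVRTPEVDDEAVEKFDKAVKALPMHVRLSFNPVQLEEQCSI
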