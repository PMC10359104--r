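fine_region,roi,roi_class
hypothalamus,hypothalamus,brainstem
medulla,medulla,brainstem
midbrain,midbrain,brainstem
pons,pons,brainstem
thalamus,thalamus,brainstem
cerebellar cortex,cerebellar cortex,cerebellum
cerebellar nuclei,cerebellar nuclei,cerebellar nuclei
pallidum,pallidum,subcortical
striatum,striatum,subcortical
cortical subplate,cortical subplate,subcortical
hippocampal formation,hippocampal formation,subcortical
olfactory areas,olfactory areas,subcortical
agranular insular area,agranular insular area,isocortex
anterior cingulate area,anterior cingulate area,isocortex
auditory areas,auditory areas,isocortex
ectorhinal area,ectorhinal area,isocortex
frontal pole,frontal pole,isocortex
infralimbic area,infralimbic area,isocortex
orbital area,orbital area,isocortex
perirhinal area,perirhinal area,isocortex
posterior parietal association areas,posterior parietal association areas,isocortex
prelimbic area,prelimbic area,isocortex
retrosplenial area,retrosplenial area,isocortex
somatomotor areas,somatomotor areas,isocortex
somatosensory areas,somatosensory areas,isocortex
temporal association areas,temporal association areas,isocortex
visual areas,visual areas,isocortex
cerebellum related fiber tracts,cerebellum related fiber tracts,white matter
cranial nerves,cranial nerves,white matter
extrapyramidal fiber system,extrapyramidal fiber system,white matter
lateral forebrain bundle system,lateral forebrain bundle system,white matter
medial forebrain bundle system,medial forebrain bundle system,white matter
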