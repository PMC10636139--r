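Benchmark confusion matrices of image-level nuclear-size classification
(rows = pathologist consensus truth; columns = prediction), as published for
the canine and feline lymphoma test sets. Classes: small, intermediate, large.

canine_unetpp.csv      workflow on canine test set, semantic segmentation backend
canine_stardist.csv    workflow on canine test set, instance segmentation backend
canine_expert_1..3.csv per-rater classification from 10 manually measured nuclei
feline_unetpp.csv      workflow on feline test set, semantic segmentation backend
feline_stardist.csv    workflow on feline test set, instance segmentation backend
feline_expert_1..3.csv per-rater classification, feline test set
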