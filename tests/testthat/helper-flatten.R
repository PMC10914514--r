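flatten_pdfs_for_test <- function(os) pairswim:::flatten_pdfs(os)
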