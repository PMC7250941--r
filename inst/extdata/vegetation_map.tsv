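label	kind
floresta ombrófila densa	forest
floresta ombrófila mista	forest
floresta estacional semidecidual	forest
floresta altomontana	forest
floresta com araucária	forest
campo de altitude	grassland
campo rupestre	grassland
campo limpo	grassland
inselberg	grassland
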