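# tiny in-code genome fixtures

# a feature row in internal coordinates
feat <- function(tag, start, end, strand = "+", protein = "MAA",
                 replicon = "chr", product = "test protein") {
  data.frame(locus_tag = tag, replicon_id = replicon, start = start,
             end = end, strand = strand, product = product,
             protein = protein)
}

tiny_genome <- function(features, length = 10000L, strain = "Test strain",
                        sequences = NULL, status = "complete",
                        replicon = "chr") {
  genome_record(strain,
                data.frame(replicon_id = replicon, length = length),
                do.call(rbind, features), sequences = sequences,
                status = status)
}
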