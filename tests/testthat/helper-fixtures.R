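# Shared fixture builders: hand-constructed alignment rows (for culling /
# selection / statistics tests, where only coordinates and scores matter)
# and a small four-rank taxonomy.

make_aln <- function(qid = "q", qstart = 0L, qend = 30L, score = 100,
                     sid = "s", sstart = 0L, send = (qend - qstart) %/% 3L,
                     strand = "+", transcript = strrep("=", send - sstart),
                     pident = 100) {
  data.frame(qid = qid, qstart = as.integer(qstart), qend = as.integer(qend),
             strand = strand, sid = sid, sstart = as.integer(sstart),
             send = as.integer(send), raw_score = score,
             bit_score = (0.267 * score - log(0.041)) / log(2),
             pident = pident, transcript = transcript,
             stringsAsFactors = FALSE)
}

# root -> phylum p1 -> genus g1 -> species {s1, s2}
#                   -> genus g2 -> species {s3}
toy_taxonomy <- function() {
  taxonomy(data.frame(
    taxon_id = c("root", "p1", "g1", "g2", "s1", "s2", "s3"),
    parent_id = c("root", "root", "p1", "p1", "g1", "g1", "g2"),
    rank = c("no rank", "phylum", "genus", "genus",
             "species", "species", "species"),
    name = c("root", "Phylum one", "Genus one", "Genus two",
             "Species one", "Species two", "Species three"),
    stringsAsFactors = FALSE))
}
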