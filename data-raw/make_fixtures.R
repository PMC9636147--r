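# Generates the packaged plain-text fixtures under inst/extdata/.
# Run from the package root: Rscript data-raw/make_fixtures.R
# Everything is deterministic (fixed seed) so the fixtures are reproducible.

set.seed(16569)
L <- 16569L

## ---- synthetic reference sequence (rCRS dimensions) ----
bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                prob = c(0.31, 0.31, 0.13, 0.25)) # mtDNA-like composition

## ---- mini haplogroup tree (phylotree-style) ----
# node parent variants(pos+alt; "@pos" = back mutation)
tree <- read.table(text = "
H2a2a1 .      .
H      H2a2a1 1438G
H3     H      6776C
H3g    H3     3915A
H3g1   H3g    6253C
H7     H      4793G
H7a    H7     9150G
H7a1   H7a    16261T
H7a1a  H7a1   3396C|@16261
H88    H      10044G
H88a   H88    5460A
H1     H      3010A
H1j    H1     13590A
H1j1   H1j    6365C
R0a    H2a2a1 2442C|13188T
JT     H2a2a1 4216C|11251G
J      JT     295T|12612G|13708A|16069T
J1     J      462T|3010A
J1b    J1     8557A
J1b3   J1b    13934T
J1b3a  J1b3   2158C
J1b3b  J1b3   9932A
J1c    J1     14798C
J1c1   J1c    482C
J1c1b  J1c1   5558T
J2     J      7476T|15257A
J2b    J2     5633T
J2b1   J2b    12406A
J2b1c  J2b1   16278T
T      JT     1888A|4917G|8697A|13368A
T2     T      11812G
U      H2a2a1 11467G|12308G|12372A
U3     U      13743C
U3b    U3     4703C
U3b1   U3b    15454C
U3b1c  U3b1   2833G|7759C|8895C|11119T|12783C|15262C
U6     U      3348G
U6a    U6     7805A
K      U      1189C|10550G|11299C|14167T
K1     K      497T
K1a    K1     10978G
K1a4   K1a    6260A
N1     H2a2a1 10238C
I      N1     10034C
W      H2a2a1 1243C
X      H2a2a1 6221C|6371T
M      H2a2a1 10400T|14783C|15043A
M5     M      12477C
M5a    M5     11884G
M5a1   M5a    2772T
M5a1b  M5a1   4454C
M5a1b1 M5a1b  5319T
M5a1b1a M5a1b1 6680C
M5a1b1a1 M5a1b1a 3921A
M18    M      12498A
M35    M      12561A
M1     M      6446A|14110C
M1a    M1     13780G
", header = FALSE, col.names = c("node", "parent", "variants"),
  stringsAsFactors = FALSE)
tree$parent[tree$parent == "."] <- ""
tree$variants[tree$variants == "."] <- ""

# published reference alleles for the clade-defining variants named in the
# literature; plant them so the rendered strings match the familiar forms
published_ref <- c(`2833` = "A", `7759` = "T", `8895` = "T", `11119` = "C",
                   `12783` = "T", `15262` = "T", `16261` = "C",
                   `4216` = "T", `11251` = "A", `295` = "C", `16069` = "C",
                   `12612` = "A", `13708` = "G", `462` = "C", `3010` = "G",
                   `11467` = "A", `12308` = "A", `12372` = "G",
                   `1438` = "A", `4917` = "A", `11812` = "A",
                   `10400` = "C", `14783` = "T", `15043` = "G",
                   `1888` = "G", `7476` = "C", `5633` = "C", `1189` = "T",
                   `10550` = "A", `11299` = "T", `14167` = "C", `497` = "C")
bases[as.integer(names(published_ref))] <- unname(published_ref)

# every tree variant must differ from the reference base at its position
vs <- setdiff(unlist(strsplit(tree$variants, "|", fixed = TRUE)), "")
vs <- vs[!startsWith(vs, "@")]
pos <- as.integer(sub("[ACGT]$", "", vs))
alt <- sub("^[0-9]+", "", vs)
for (i in seq_along(pos)) {
  if (bases[pos[i]] == alt[i]) {
    bases[pos[i]] <- setdiff(c("A", "C", "G", "T"), alt[i])[1]
  }
}

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
seqstr <- paste(bases, collapse = "")
writeLines(c(
  ">synthetic_rCRS synthetic stand-in reference, rCRS dimensions (16569 bp)",
  substring(seqstr, seq(1, L, 70), pmin(seq(1, L, 70) + 69, L))),
  "inst/extdata/synthetic_rcrs.fasta")

# render tree with reference alleles attached (A2833G style)
render <- function(s) {
  if (!nzchar(s)) return("")
  v <- strsplit(s, "|", fixed = TRUE)[[1]]
  out <- vapply(v, function(x) {
    if (startsWith(x, "@")) return(x)
    p <- as.integer(sub("[ACGT]$", "", x))
    paste0(bases[p], x)
  }, "")
  paste(out, collapse = " ")
}
tree$variants <- vapply(tree$variants, render, "")
writeLines(c("# synthetic phylotree-style mini-tree fixture;",
             "# clade-defining variants follow published forms where available,",
             "# backbone assignments are synthetic.",
             "node\tparent\tvariants",
             sprintf("%s\t%s\t%s", tree$node, tree$parent, tree$variants)),
           "inst/extdata/minitree.tsv")

## ---- gene annotation (published rCRS coordinates) ----
genes <- "gene\tstart\tend\tstrand\ttype
RNR1\t648\t1601\t+\trRNA
RNR2\t1671\t3229\t+\trRNA
ND1\t3307\t4262\t+\tprotein
ND2\t4470\t5511\t+\tprotein
CO1\t5904\t7445\t+\tprotein
CO2\t7586\t8269\t+\tprotein
ATP8\t8366\t8572\t+\tprotein
ATP6\t8527\t9207\t+\tprotein
CO3\t9207\t9990\t+\tprotein
ND3\t10059\t10404\t+\tprotein
ND4L\t10470\t10766\t+\tprotein
ND4\t10760\t12137\t+\tprotein
ND5\t12337\t14148\t+\tprotein
ND6\t14149\t14673\t-\tprotein
CYTB\t14747\t15887\t+\tprotein
CR_a\t16024\t16569\t+\tcontrol
CR_b\t1\t576\t+\tcontrol"
writeLines(c("# rCRS gene coordinates (1-based inclusive); the control region",
             "# spans the origin of the circular molecule (16024-16569 + 1-576).",
             genes), "inst/extdata/rcrs_genes.tsv")

## ---- hotspot list ----
hot <- c(146, 150, 152, 195, 309, 310, 315, 455, 460,
         16093, 16129, 16182, 16183, 16189, 16193, 16311, 16362, 16519)
writeLines(c("# hypervariable / mutational hotspot positions excluded from",
             "# founder definitions, haplogroup scoring and clade dating",
             as.character(hot)), "inst/extdata/hotspots.txt")

## ---- macrogroup prefix table ----
writeLines(c("# longest-prefix ancestry classification of haplogroup labels",
             "prefix\tclass",
             "M\tSouth Asian",
             "M1\tNorth African",
             "U6\tNorth African",
             paste0(c("U", "K", "H", "V", "HV", "R0", "JT", "J", "T",
                      "N1", "N2", "W", "X", "I"), "\tWest Eurasian")),
           "inst/extdata/macrogroups.tsv")

## ---- purifying-selection clock calibration (synthetic) ----
writeLines(c(
  "# Synthetic calibration of the time-dependent clock correction.",
  "# Model: expected substitutions rho(t) = mu*L*((1-f)*t + f*tau*(1-exp(-t/tau)))",
  "# f    = fraction of new mutations transiently tolerated but eventually",
  "#        purged by purifying selection; chosen so the long-term rate",
  "#        (1-f)*mu equals 1.665e-8 subs/site/yr when mu = 2.355e-8",
  "# tau  = purging timescale in years",
  "param\tvalue",
  "f\t0.29299",
  "tau_years\t12000"), "inst/extdata/selection_curve_synthetic.tsv")

## ---- small synthetic pathogenicity score table ----
mito_code <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="M",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="W",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="*",AGG="*",GGT="G",GGC="G",GGA="G",GGG="G")
gtab <- read.delim(text = genes, stringsAsFactors = FALSE)
prot <- gtab[gtab$type == "protein" & gtab$strand == "+", ]
rows <- list()
for (i in 1:40) {
  g <- prot[sample(nrow(prot), 1), ]
  ncod <- (g$end - g$start + 1) %/% 3
  cidx <- sample(ncod, 1)
  cstart <- g$start + (cidx - 1) * 3
  codon <- paste(bases[cstart:(cstart + 2)], collapse = "")
  off <- sample(0:2, 1)
  p <- cstart + off
  for (nb in setdiff(c("A", "C", "G", "T"), bases[p])) {
    cod2 <- codon
    substr(cod2, off + 1, off + 1) <- nb
    if (mito_code[[cod2]] != mito_code[[codon]] &&
        mito_code[[cod2]] != "*") {
      rows[[length(rows) + 1]] <- data.frame(
        position = p, ref_aa = mito_code[[codon]],
        alt_aa = mito_code[[cod2]],
        score = round(runif(1), 3), stringsAsFactors = FALSE)
    }
  }
}
ptab <- unique(do.call(rbind, rows))
ptab <- ptab[!duplicated(ptab[, 1:3]), ]
write.table(ptab, "inst/extdata/pathogenicity_synthetic.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## ---- report schema ----
writeLines(jsonlite::toJSON(list(
  required = c("diversity", "haplogroup_composition", "founder_lineages",
               "founder_fractions", "ages", "amova", "amova_no_founders",
               "composition_chi2", "pathogenicity", "provenance")),
  pretty = TRUE), "inst/extdata/report_schema.json")

cat("fixtures written\n")
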