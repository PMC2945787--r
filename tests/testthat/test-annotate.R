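test_that("PDF/POF classification is a partition driven by domains", {
    a <- makeAnnotationTable(
        tu_id = c("T1", "T2", "T3"),
        domain_ids = list("IPR000719", character(0), c("IPR1", "IPR2")))
    cls <- classifyPofPdf(a)
    expect_identical(unname(cls), c("PDF", "POF", "PDF"))
    expect_true(all(cls %in% c("PDF", "POF")))

    # genome-scale shares: 5,825 domain-bearing of 10,402 gives 44% POFs
    n <- 10402L; nPdf <- 5825L
    big <- makeAnnotationTable(
        tu_id = sprintf("T%05d", seq_len(n)),
        domain_ids = c(rep(list("IPR000001"), nPdf),
                       rep(list(character(0)), n - nPdf)))
    pofPct <- 100 * mean(classifyPofPdf(big) == "POF")
    expect_equal(round(pofPct), 44)
})

test_that("annotation tables round-trip through TSV", {
    tmp <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c(
        "tu_id\tdomain_ids\tgo_terms\tphyletic_class\tcog_class",
        "T1\tIPR1;IPR2\tGO:0000001\tcore\tC",
        "T2\t\tGO:0000001;GO:0000002\tdiatom_specific\t",
        "T3\t\t\tweird\t"), tmp)
    a <- readAnnotationTable(tmp)
    expect_identical(unlist(a["T1", "domain_ids"]), c("IPR1", "IPR2"))
    expect_length(unlist(a["T2", "domain_ids"]), 0L)
    expect_identical(a["T3", "phyletic_class"], "unclassified")
    expect_true(is.na(a["T2", "cog_class"]))
    expect_error(makeAnnotationTable(c("T1", "T1")), "duplicate")
})

test_that("enrichment p-values equal exhaustive hypergeometric sums", {
    # worked example: background 10, term in 5, DE set of 2 both with term
    a <- makeAnnotationTable(
        tu_id = paste0("T", 1:10),
        go_terms = c(rep(list("GO:1"), 5), rep(list(character(0)), 5)))
    res <- goEnrichment(c("T1", "T2"), paste0("T", 1:10), a)
    expect_equal(res$p_value[res$term_id == "GO:1"],
                 choose(5, 2) / choose(10, 2))

    # de set = background: no enrichment possible, all p = 1
    resAll <- goEnrichment(paste0("T", 1:10), paste0("T", 1:10), a)
    expect_true(all(resAll$p_value == 1))
    expect_false(any(resAll$significant))

    # random tables with margins <= 60 vs explicit choose() sums
    set.seed(66)
    for (i in 1:25) {
        nBg <- sample(10:60, 1)
        kBg <- sample(1:nBg, 1)
        nDe <- sample(1:nBg, 1)
        ids <- paste0("T", seq_len(nBg))
        withTerm <- sample(ids, kBg)
        de <- sample(ids, nDe)
        ann <- makeAnnotationTable(ids,
            go_terms = lapply(ids, function(t)
                if (t %in% withTerm) "GO:X" else character(0)))
        p <- goEnrichment(de, ids, ann)$p_value[1]
        kDe <- sum(de %in% withTerm)
        expect_equal(p, hyperUpperBrute(kDe, kBg, nBg, nDe),
                     tolerance = 1e-12)
    }
    expect_error(goEnrichment("T1", character(0), a), "empty background")
    expect_error(goEnrichment("T99", paste0("T", 1:10), a), "subset")
})

test_that("enrichment is monotone in DE-set term content", {
    ids <- paste0("T", 1:40)
    withTerm <- ids[1:12]
    ann <- makeAnnotationTable(ids,
        go_terms = lapply(ids, function(t)
            if (t %in% withTerm) "GO:X" else character(0)))
    # fix |de| = 10; move term-bearing TUs in one at a time
    pPrev <- Inf
    for (k in 0:10) {
        de <- c(withTerm[seq_len(k)],
                setdiff(ids, withTerm)[seq_len(10 - k)])
        p <- goEnrichment(de, ids, ann)$p_value[1]
        expect_lte(p, pPrev + 1e-12)
        pPrev <- p
    }
})

test_that("planted enriched terms are recovered at alpha 0.001", {
    hits <- 0L
    for (seed in 1:20) {
        set.seed(seed)
        nBg <- 2000L
        ids <- sprintf("T%04d", seq_len(nBg))
        de <- sample(ids, 100L)
        # term at 5% baseline, loaded 5x into the DE set
        pTerm <- ifelse(ids %in% de, 0.25, 0.05)
        ann <- makeAnnotationTable(ids,
            go_terms = lapply(seq_len(nBg), function(i)
                if (runif(1) < pTerm[i]) "GO:LOADED" else character(0)))
        res <- goEnrichment(de, ids, ann, alpha = 0.001)
        if (res[res$term_id == "GO:LOADED", "significant"]) hits <- hits + 1L
    }
    expect_gte(hits, 19L)
})

test_that("class profiles average back to the column mean over a partition", {
    set.seed(77)
    m <- randomCountMatrix(60, 4)
    cls <- rep(c("core", "species_specific"), each = 30)
    ann <- makeAnnotationTable(rownames(m), phyletic_class = cls)
    x <- ESTCountSet(m)
    cp <- classProfile(x, ann)
    f <- estFrequencies(x)
    # two classes partition the rows; size-weighted average of class
    # means reproduces the overall column mean
    w <- table(cls)[rownames(cp)]
    back <- colSums(cp * as.numeric(w)) / sum(w)
    expect_equal(back, colMeans(f), tolerance = 1e-12)

    # planted abundance ordering: core TUs at 3x scale dominate per library
    s <- simulateLibraries(nTUs = 3000, seed = 88,
                           classProportions = c(core = 0.5,
                                                species_specific = 0.5),
                           classAbundance = c(core = 3,
                                              species_specific = 1))
    cp2 <- classProfile(s$counts, s$annotation)
    expect_true(all(cp2["core", ] > cp2["species_specific", ]))
})

test_that("ortholog overlap counts direct and degenerate cases", {
    ov <- orthologOverlap(c("t1", "t2"),
                          setB = "g1",
                          pairs = data.frame(a_id = "t1", b_id = "g1"))
    expect_equal(ov$n_de_a, 2L)
    expect_equal(ov$n_with_ortholog, 1L)
    expect_equal(ov$n_overlap, 1L)

    empty <- orthologOverlap(c("t1", "t2"), "g1",
                             data.frame(a_id = character(0),
                                        b_id = character(0)))
    expect_equal(empty$n_with_ortholog, 0L)
    expect_equal(empty$n_overlap, 0L)

    # planted conserved-responder fraction is recovered
    set.seed(12)
    tus <- sprintf("T%04d", 1:2000)
    de <- sample(tus, 300)
    sim <- simulateOrthologPairs(tus, de, orthologRate = 0.6,
                                 conservedFraction = 0.4, seed = 12)
    ov2 <- orthologOverlap(de, sim$setB, sim$pairs)
    frac <- ov2$n_overlap / ov2$n_with_ortholog
    se <- sqrt(0.4 * 0.6 / ov2$n_with_ortholog)
    expect_lt(abs(frac - 0.4), 4 * se)
})

test_that("COG summaries cover only categorized TUs", {
    m <- randomCountMatrix(10, 3)
    ann <- makeAnnotationTable(rownames(m),
        cog_class = c(rep("C", 4), rep("E", 3), rep(NA, 3)))
    cs <- cogSummary(ESTCountSet(m), ann)
    expect_setequal(cs$cog_class, c("C", "E"))
    expect_equal(sum(cs$n_tus), 7L)
})
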