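test_that("identical profiles merge first at height zero", {
    set.seed(4)
    m <- cbind(A = c(1, 2, 3, 4), B = c(2, 4, 6, 8),  # proportional: d = 0
               C = c(9, 1, 1, 1), D = c(1, 9, 2, 1))
    rownames(m) <- paste0("T", 1:4)
    hc <- hierarchicalCluster(m, axis = "columns")
    expect_equal(hc$height[1], 0, tolerance = 1e-12)
    first <- sort(hc$labels[-hc$merge[1, ]])
    expect_identical(first, c("A", "B"))
})

test_that("planted groups are recovered and clustering is permutation-equivariant", {
    set.seed(14)
    g1 <- matrix(rep(c(10, 10, 1, 1), each = 2), 2, byrow = FALSE)
    base <- rbind(c(10, 9, 1, 1), c(9, 10, 1, 2),
                  c(1, 1, 10, 9), c(1, 2, 9, 10))
    rownames(base) <- paste0("I", 1:4); colnames(base) <- paste0("L", 1:4)
    hc <- hierarchicalCluster(base, axis = "rows")
    # the first two merges are within the planted groups
    withinGroup <- function(pair) {
        labs <- rownames(base)[-pair]
        all(labs %in% c("I1", "I2")) || all(labs %in% c("I3", "I4"))
    }
    expect_true(withinGroup(hc$merge[1, ]))
    expect_true(withinGroup(hc$merge[2, ]))

    # pairwise-distance oracle: the closest pair merges first
    d <- as.matrix(profileDist(base))
    diag(d) <- Inf
    closest <- sort(rownames(base)[which(d == min(d), arr.ind = TRUE)[1, ]])
    expect_identical(sort(rownames(base)[-hc$merge[1, ]]), closest)

    # permuting input rows permutes leaf labels identically
    perm <- c(3, 1, 4, 2)
    hcp <- hierarchicalCluster(base[perm, ], axis = "rows")
    expect_identical(sort(hcp$labels[hcp$order]), sort(hc$labels[hc$order]))
    cop <- stats::cophenetic(hc); copP <- stats::cophenetic(hcp)
    ids <- rownames(base)
    expect_equal(as.matrix(copP)[ids, ids], as.matrix(cop)[ids, ids],
                 tolerance = 1e-12)
})

test_that("libraries sharing a planted signature form a clade", {
    s <- simulateLibraries(nTUs = 800, nLibraries = 8,
                           librarySizes = rep(4000L, 8),
                           deFraction = 0, seed = 25)
    m <- estCounts(s$counts)
    # spike a shared perturbation signature into libraries 1-4
    sig <- seq_len(40)
    m[sig, 1:4] <- m[sig, 1:4] + 60L
    hc <- hierarchicalCluster(normalizeFrequencies(m), axis = "columns")
    k2 <- stats::cutree(hc, k = 2)
    expect_equal(length(unique(k2[1:4])), 1L)
    expect_true(all(k2[5:8] != k2[1]))
})

test_that("clustering rejects degenerate inputs", {
    m <- rbind(Z = c(0, 0, 0), A = c(1, 2, 3), B = c(3, 2, 1))
    expect_error(hierarchicalCluster(m, distance = "uncentered"), "'Z'")
    m2 <- rbind(K = c(2, 2, 2), A = c(1, 2, 3), B = c(3, 2, 1))
    expect_error(hierarchicalCluster(m2, distance = "pearson"), "'K'")
    expect_error(profileDist(m[1, , drop = FALSE]), "2 items")
})

test_that("correspondence analysis matches independent oracles", {
    # identical rows: independence, zero inertia
    flat <- matrix(rep(c(2, 3, 5), 4), 4, byrow = TRUE,
                   dimnames = list(paste0("r", 1:4), paste0("c", 1:3)))
    ca0 <- correspondenceAnalysis(flat)
    expect_equal(totalInertia(ca0), 0, tolerance = 1e-12)
    expect_equal(ncol(rowCoords(ca0)), 0L)

    # 2x2 diagonal: a single axis carries all the inertia
    d2 <- matrix(c(10, 0, 0, 10), 2,
                 dimnames = list(c("a", "b"), c("x", "y")))
    ca2 <- correspondenceAnalysis(d2)
    expect_equal(length(inertiaFractions(ca2)), 1L)
    expect_equal(inertiaFractions(ca2)[1], 1)

    set.seed(33)
    for (i in 1:5) {
        m <- matrix(rpois(100, 5) + 1, 20, 5,
                    dimnames = list(paste0("r", 1:20), paste0("c", 1:5)))
        ca <- correspondenceAnalysis(m)
        oracle <- caInertiaOracle(m)
        expect_equal(unname(ca@inertia), oracle[seq_along(ca@inertia)],
                     tolerance = 1e-8)
        # total inertia = chi-square statistic / grand total
        chi <- suppressWarnings(stats::chisq.test(m)$statistic)
        expect_equal(totalInertia(ca), unname(chi) / sum(m),
                     tolerance = 1e-8)
        # mass-weighted coordinate means vanish on every axis
        r <- rowSums(m) / sum(m); cc <- colSums(m) / sum(m)
        expect_equal(max(abs(crossprod(rowCoords(ca), r))), 0,
                     tolerance = 1e-8)
        expect_equal(max(abs(crossprod(colCoords(ca), cc))), 0,
                     tolerance = 1e-8)
    }
})

test_that("CA cross-checks against MASS::corresp and frequency equivalence", {
    skip_if_not_installed("MASS")
    set.seed(44)
    m <- matrix(rpois(60, 6) + 1, 12, 5,
                dimnames = list(paste0("r", 1:12), paste0("c", 1:5)))
    ca <- correspondenceAnalysis(m)
    mc <- MASS::corresp(m, nf = 4)
    expect_equal(unname(ca@singularValues[1:4]), unname(mc$cor[1:4]),
                 tolerance = 1e-8)

    # equal library sizes: CA of counts equals CA of frequencies
    meq <- matrix(rpois(60, 6) + 1, 12, 5)
    meq[12, ] <- meq[12, ] + max(colSums(meq)) - colSums(meq)
    dimnames(meq) <- list(paste0("r", 1:12), paste0("c", 1:5))
    stopifnot(length(unique(colSums(meq))) == 1L)
    caC <- correspondenceAnalysis(meq)
    caF <- correspondenceAnalysis(normalizeFrequencies(meq))
    expect_equal(caC@inertia, caF@inertia, tolerance = 1e-6)
})

test_that("TreeView export writes consistent CDT/GTR/ATR triples", {
    set.seed(55)
    f <- matrix(runif(9), 3, dimnames = list(paste0("T", 1:3),
                                             paste0("L", 1:3)))
    f <- sweep(f, 2, colSums(f), "/")
    hr <- hierarchicalCluster(f, "rows", distance = "euclidean")
    hc <- hierarchicalCluster(f, "columns", distance = "euclidean")
    base <- file.path(withr::local_tempdir(), "out")
    files <- exportTreeview(f, hr, hc, basePath = base)
    expect_true(all(file.exists(files)))

    cdt <- readLines(files["cdt"])
    # header + AID + EWEIGHT + 3 data rows
    expect_length(cdt, 6L)
    # skip header, AID and EWEIGHT preamble lines
    dat <- read.delim(files["cdt"], skip = 3, header = FALSE)
    expect_equal(nrow(dat), 3L)
    # re-read frequencies equal written ones (up to leaf reordering)
    vals <- as.matrix(dat[, 5:7])
    dimnames(vals) <- list(dat[[2]], strsplit(cdt[1], "\t")[[1]][5:7])
    expect_equal(vals[rownames(f), colnames(f)], f, tolerance = 1e-9)

    gtr <- read.delim(files["gtr"], header = FALSE)
    expect_equal(nrow(gtr), 2L)   # n - 1 merges
    # every node/leaf id referenced exactly once as a child
    kids <- c(gtr$V2, gtr$V3)
    expect_equal(sort(kids),
                 sort(c(paste0("GENE", 1:3, "X"), "NODE1X")))
    expect_error(exportTreeview(f[1:2, ], hr, hc, basePath = base),
                 "row dendrogram")
})
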