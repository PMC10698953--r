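# Shared fixtures and independent oracles, built in code at test time.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
    if (is.null(.fixture_env[[key]]))
        .fixture_env[[key]] <- force(expr)
    .fixture_env[[key]]
}

# unit cube surface: 8 corners, 12 triangles, outward winding
cubeMesh <- function(side = 1) {
    v <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
    dimnames(v) <- NULL
    f <- rbind(
        c(1, 3, 2), c(2, 3, 4),   # z = 0
        c(5, 6, 7), c(6, 8, 7),   # z = side
        c(1, 2, 5), c(2, 6, 5),   # y = 0
        c(3, 7, 4), c(4, 7, 8),   # y = side
        c(1, 5, 3), c(3, 5, 7),   # x = 0
        c(2, 4, 6), c(4, 8, 6))   # x = side
    cleanMesh(TriangleMesh(v, f), warn = FALSE)
}

# flat regular grid (z = 0), consistent diagonal split; interior
# vertices sit exactly at their neighbour centroid
gridMesh <- function(n = 8) {
    v <- as.matrix(expand.grid(x = 0:(n - 1), y = 0:(n - 1)))
    v <- cbind(v, 0)
    dimnames(v) <- NULL
    idx <- function(i, j) (j - 1) * n + i
    faces <- list()
    for (j in 1:(n - 1)) for (i in 1:(n - 1)) {
        a <- idx(i, j); b <- idx(i + 1, j)
        c_ <- idx(i, j + 1); d <- idx(i + 1, j + 1)
        faces[[length(faces) + 1]] <- rbind(c(a, b, c_), c(b, d, c_))
    }
    TriangleMesh(v, do.call(rbind, faces))
}

# brute-force TFCE: explicit loop over heights and connected
# components (igraph), independent of the compiled path
bruteTFCE <- function(stat, mesh, E = 1, H = 2, dh) {
    g <- vertexGeometry(mesh)
    gr <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0, nVertices(mesh) -
                                       igraph::vcount(gr)))
    one_sided <- function(s) {
        out <- numeric(length(s))
        hmax <- max(s)
        if (hmax <= 0) return(out)
        nh <- floor(hmax / dh * (1 + 1e-12) + 1e-9)
        for (k in seq_len(nh)) {
            h <- k * dh
            act <- which(s >= h)
            if (!length(act)) next
            sub <- igraph::induced_subgraph(gr, act)
            comp <- igraph::components(sub)$membership
            for (ci in unique(comp)) {
                vs <- act[comp == ci]
                out[vs] <- out[vs] + sum(g$areas[vs])^E * h^H * dh
            }
        }
        out
    }
    one_sided(pmax(stat, 0)) - one_sided(pmax(-stat, 0))
}

# per-vertex OLS by explicit normal equations, no shared code with
# fitMUR's vectorised path
olsOracle <- function(Y, X) {
    p <- ncol(X); nv <- ncol(Y); n <- nrow(Y)
    beta <- matrix(NA_real_, p, nv)
    tstat <- matrix(NA_real_, p, nv)
    for (v in seq_len(nv)) {
        xtx <- t(X) %*% X
        b <- solve(xtx, t(X) %*% Y[, v])
        r <- Y[, v] - X %*% b
        s2 <- sum(r^2) / (n - p)
        se <- sqrt(diag(solve(xtx)) * s2)
        beta[, v] <- b
        tstat[, v] <- b / se
    }
    list(beta = beta, tstat = tstat)
}

smallSphere <- function() cached("sphere300", sphereMesh(300, radius = 10))
smallTemplate <- function() cached("tpl150", generateTemplateShape(150))
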