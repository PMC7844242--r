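/* Two-pass union-find connected-components labeling for binary masks.
 * Masks are R matrices (column-major, H x W); labels are assigned in
 * row-major first-touch order so that label 1 is the puddle whose first
 * pixel comes earliest in a row-by-row scan. Connectivity 4 or 8. */

#include <R.h>
#include <Rinternals.h>

static int uf_find(int *parent, int i)
{
    int root = i;
    while (parent[root] != root) root = parent[root];
    while (parent[i] != root) { int next = parent[i]; parent[i] = root; i = next; }
    return root;
}

static void uf_union(int *parent, int *rank, int a, int b)
{
    int ra = uf_find(parent, a), rb = uf_find(parent, b);
    if (ra == rb) return;
    if (rank[ra] < rank[rb]) { int t = ra; ra = rb; rb = t; }
    parent[rb] = ra;
    if (rank[ra] == rank[rb]) rank[ra]++;
}

SEXP C_label_components(SEXP mask_, SEXP h_, SEXP w_, SEXP connectivity_,
                        SEXP periodic_)
{
    const int h = asInteger(h_), w = asInteger(w_);
    const int conn = asInteger(connectivity_);
    const int periodic = asLogical(periodic_);
    const int *mask = LOGICAL(mask_);
    if ((R_xlen_t)h * w != xlength(mask_))
        error("mask length does not match dimensions");
    if (conn != 4 && conn != 8)
        error("connectivity must be 4 or 8");

    int *parent = (int *) R_alloc((size_t)h * w, sizeof(int));
    int *rank = (int *) R_alloc((size_t)h * w, sizeof(int));

    /* first pass: row-major scan, union with already-seen neighbours */
    for (int r = 0; r < h; r++) {
        for (int c = 0; c < w; c++) {
            int i = r + c * h;
            if (mask[i] == NA_LOGICAL)
                error("mask contains NA");
            if (!mask[i]) continue;
            parent[i] = i;
            rank[i] = 0;
            /* up */
            if (r > 0 && mask[i - 1]) uf_union(parent, rank, i, i - 1);
            /* left */
            if (c > 0 && mask[i - h]) uf_union(parent, rank, i, i - h);
            if (conn == 8) {
                /* up-left */
                if (r > 0 && c > 0 && mask[i - 1 - h]) uf_union(parent, rank, i, i - 1 - h);
                /* up-right */
                if (r > 0 && c < w - 1 && mask[i - 1 + h]) uf_union(parent, rank, i, i - 1 + h);
            }
        }
    }

    /* periodic boundary: union wrapped neighbour pairs (torus topology) */
    if (periodic && h > 1 && w > 1) {
        for (int c = 0; c < w; c++) {
            int bottom = (h - 1) + c * h;
            if (!mask[bottom]) continue;
            int lo = (conn == 8) ? c - 1 : c, hi = (conn == 8) ? c + 1 : c;
            for (int cc = lo; cc <= hi; cc++) {
                int cw = (cc + w) % w;
                int top = 0 + cw * h;
                if (mask[top]) uf_union(parent, rank, bottom, top);
            }
        }
        for (int r = 0; r < h; r++) {
            int right = r + (w - 1) * h;
            if (!mask[right]) continue;
            int lo = (conn == 8) ? r - 1 : r, hi = (conn == 8) ? r + 1 : r;
            for (int rr = lo; rr <= hi; rr++) {
                int rw = (rr + h) % h;
                int left = rw + 0 * h;
                if (mask[left]) uf_union(parent, rank, right, left);
            }
        }
    }

    SEXP labels_ = PROTECT(allocMatrix(INTSXP, h, w));
    int *labels = INTEGER(labels_);
    memset(labels, 0, (size_t)h * w * sizeof(int));

    /* second pass: assign labels 1..n in row-major first-touch order */
    int next = 0;
    for (int r = 0; r < h; r++) {
        for (int c = 0; c < w; c++) {
            int i = r + c * h;
            if (!mask[i]) continue;
            int root = uf_find(parent, i);
            if (labels[root] == 0) labels[root] = ++next;
            if (i != root) labels[i] = labels[root];
        }
    }
    /* roots kept their own slot; pixels already filled above */
    for (int r = 0; r < h; r++)
        for (int c = 0; c < w; c++) {
            int i = r + c * h;
            if (mask[i] && labels[i] == 0) labels[i] = labels[uf_find(parent, i)];
        }

    SEXP out = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(out, 0, labels_);
    SET_VECTOR_ELT(out, 1, ScalarInteger(next));
    UNPROTECT(2);
    return out;
}
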