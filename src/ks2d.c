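/* D statistic of the two-sample two-dimensional Kolmogorov-Smirnov test
 * (Fasano & Franceschini variant): for anchors taken at the data points of
 * each sample, compare the fractions of the two samples in the four
 * quadrants around the anchor; D is the average of the two
 * sample-anchored maxima. Points lying exactly on a dividing line are
 * split evenly between the two sides.
 */
#include <R.h>
#include <Rinternals.h>

static double quad_max_diff(double x0, double y0,
                            const double *xa, const double *ya, int na,
                            const double *xb, const double *yb, int nb)
{
    double qa[4] = {0, 0, 0, 0}, qb[4] = {0, 0, 0, 0};
    for (int i = 0; i < na; i++) {
        double wx = xa[i] > x0 ? 1.0 : (xa[i] == x0 ? 0.5 : 0.0);
        double wy = ya[i] > y0 ? 1.0 : (ya[i] == y0 ? 0.5 : 0.0);
        qa[0] += wx * wy;
        qa[1] += (1 - wx) * wy;
        qa[2] += (1 - wx) * (1 - wy);
        qa[3] += wx * (1 - wy);
    }
    for (int i = 0; i < nb; i++) {
        double wx = xb[i] > x0 ? 1.0 : (xb[i] == x0 ? 0.5 : 0.0);
        double wy = yb[i] > y0 ? 1.0 : (yb[i] == y0 ? 0.5 : 0.0);
        qb[0] += wx * wy;
        qb[1] += (1 - wx) * wy;
        qb[2] += (1 - wx) * (1 - wy);
        qb[3] += wx * (1 - wy);
    }
    double d = 0.0;
    for (int q = 0; q < 4; q++) {
        double diff = qa[q] / na - qb[q] / nb;
        if (diff < 0) diff = -diff;
        if (diff > d) d = diff;
    }
    return d;
}

SEXP mxpol_ks2d_d(SEXP xa_, SEXP ya_, SEXP xb_, SEXP yb_)
{
    int na = LENGTH(xa_), nb = LENGTH(xb_);
    const double *xa = REAL(xa_), *ya = REAL(ya_);
    const double *xb = REAL(xb_), *yb = REAL(yb_);
    double d1 = 0.0, d2 = 0.0;
    for (int i = 0; i < na; i++) {
        double d = quad_max_diff(xa[i], ya[i], xa, ya, na, xb, yb, nb);
        if (d > d1) d1 = d;
    }
    for (int i = 0; i < nb; i++) {
        double d = quad_max_diff(xb[i], yb[i], xa, ya, na, xb, yb, nb);
        if (d > d2) d2 = d;
    }
    return ScalarReal(0.5 * (d1 + d2));
}
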