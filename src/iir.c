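#include <R.h>
#include <Rinternals.h>

/* Direct-form-II-transposed IIR filter.
 * b, a: coefficient vectors, a[0] must be 1 (caller normalizes).
 * Single pass, zero initial conditions.
 */
SEXP C_iir_filter(SEXP b_, SEXP a_, SEXP x_)
{
    const double *b = REAL(b_), *a = REAL(a_), *x = REAL(x_);
    const R_xlen_t nb = XLENGTH(b_), na = XLENGTH(a_), n = XLENGTH(x_);
    R_xlen_t nz = (nb > na ? nb : na) - 1;
    if (nz < 1) nz = 1;

    SEXP y_ = PROTECT(allocVector(REALSXP, n));
    double *y = REAL(y_);
    double *z = (double *) R_alloc(nz, sizeof(double));
    for (R_xlen_t i = 0; i < nz; i++) z[i] = 0.0;

    for (R_xlen_t t = 0; t < n; t++) {
        double xt = x[t];
        double yt = b[0] * xt + z[0];
        for (R_xlen_t i = 0; i < nz - 1; i++) {
            double bi = (i + 1 < nb) ? b[i + 1] : 0.0;
            double ai = (i + 1 < na) ? a[i + 1] : 0.0;
            z[i] = bi * xt - ai * yt + z[i + 1];
        }
        double bl = (nz < nb) ? b[nz] : 0.0;
        double al = (nz < na) ? a[nz] : 0.0;
        z[nz - 1] = bl * xt - al * yt;
        y[t] = yt;
    }
    UNPROTECT(1);
    return y_;
}
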