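/* Compiled right-hand side of the P-C-S-F system for deSolve.
 *
 * State y = (P, C, S, F).  Within one integration segment gamma(t) is
 * linear: gamma = g0 + g1 * t (pulse edges are handled by the R driver,
 * which restarts the solver at discontinuities).
 *
 * parms:
 *  0 r        proliferation rate (already zeroed after the extinction event)
 *  1 f1       P -> C rate scale
 *  2 f2       C -> P rate
 *  3 f3       C -> S rate
 *  4 K        response normalization (arrest flux uses F/K)
 *  5 a        feedback amplitude of dF/dt
 *  6 b        feedback half-saturation
 *  7 c        linear decay rate of F
 *  8 g0       gamma offset on this segment
 *  9 g1       gamma slope on this segment
 * 10 fhat     if >= 0, hold the normalized response fixed at this value
 *             (constant-stress / reduced-model mode); if < 0, dynamic F
 * 11 thresh   extinction root threshold for P (root: P - thresh)
 */
#include <R.h>

static double parms[12];
#define p_r      parms[0]
#define p_f1     parms[1]
#define p_f2     parms[2]
#define p_f3     parms[3]
#define p_K      parms[4]
#define p_a      parms[5]
#define p_b      parms[6]
#define p_c      parms[7]
#define p_g0     parms[8]
#define p_g1     parms[9]
#define p_fhat   parms[10]
#define p_thresh parms[11]

void pcs_initmod(void (*odeparms)(int *, double *))
{
    int n = 12;
    odeparms(&n, parms);
}

void pcs_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double P = y[0], C = y[1], F = y[3];
    double fhat = (p_fhat >= 0.0) ? p_fhat : F / p_K;
    double flux_in = p_f1 * fhat * P;  /* P -> C */
    double flux_out = p_f2 * C;        /* C -> P */

    ydot[0] = p_r * P - flux_in + flux_out;
    ydot[1] = flux_in - flux_out - p_f3 * C;
    ydot[2] = p_f3 * C;
    if (p_fhat >= 0.0) {
        ydot[3] = 0.0;
    } else {
        double gamma = p_g0 + p_g1 * (*t);
        ydot[3] = gamma + p_a * F * F / (p_b * p_b + F * F) - p_c * F;
    }
}

void pcs_root(int *neq, double *t, double *y, int *ng, double *gout)
{
    gout[0] = y[0] - p_thresh;
}
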