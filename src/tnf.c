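/* Four-state TNF signaling model: relative activities of C8a, C3a,
 * NF-kB and I-kB.  Activating and inhibiting interactions are Hill-type
 * with exponent 2,
 *   act(x, a) = x^2 / (a^2 + x^2),   inh(x, b) = b^2 / (b^2 + x^2),
 * both taking values in [0, 1].  Compiled derivative function for use
 * with deSolve (dllname = "popsnap").
 *
 * Parameter vector (10): a1..a4, b1..b5, u (TNF stimulus level).
 */

#include <R.h>

static double parms[10];

#define P_A1 parms[0]
#define P_A2 parms[1]
#define P_A3 parms[2]
#define P_A4 parms[3]
#define P_B1 parms[4]
#define P_B2 parms[5]
#define P_B3 parms[6]
#define P_B4 parms[7]
#define P_B5 parms[8]
#define P_U  parms[9]

void tnf_initmod(void (*odeparms)(int *, double *)) {
    int n = 10;
    odeparms(&n, parms);
}

static double actf(double x, double a) {
    if (x <= 0.0) return 0.0;
    return x * x / (a * a + x * x);
}

static double inhf(double x, double b) {
    double xp = x > 0.0 ? x : 0.0;
    double den = b * b + xp * xp;
    if (den <= 0.0) return 1.0;   /* degenerate threshold, no inhibitor */
    return b * b / den;
}

void tnf_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip) {
    /* x1 C8a: activated by TNF, inhibited by NF-kB (via FLIP) */
    ydot[0] = -y[0] + actf(P_U, P_A1) * inhf(y[2], P_B1);
    /* x2 C3a: activated by C8a, inhibited by NF-kB (via XIAP, b3) */
    ydot[1] = -y[1] + actf(y[0], P_A2) * inhf(y[2], P_B3);
    /* x3 NF-kB: activated by TNF, inhibited by C3a and I-kB */
    ydot[2] = -y[2] + actf(P_U, P_A3) * inhf(y[1], P_B2) * inhf(y[3], P_B4);
    /* x4 I-kB: activated by NF-kB (a4), inhibited by C3a */
    ydot[3] = -y[3] + actf(y[2], P_A4) * inhf(y[1], P_B5);
}
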