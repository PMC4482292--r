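/* Compiled right-hand side of the modular Rab5/Rab7 conversion system,
 * in the deSolve compiled-code calling convention.
 *
 * Parameter vector layout (29 doubles), kept in step with rhs_parms() on
 * the R side:
 *   [0..3]  K1, k1, K2, k2
 *   then five blocks of five for the rate-law components
 *   gef5, gap5, gef7_cross, gef7_auto, gap7:
 *     [kind, regulator, p1, p2, p3]
 *   kind: 0 absent, 1 intrinsic, 2 Michaelis-Menten, 3 sigmoidal,
 *         4 exchange inhibition, 5 linear
 *   regulator: 0 none, 1 active Rab5 (R5), 2 active Rab7 (R7)
 *   p1 = k or V, p2 = Km, p3 = Hill exponent h (sigmoidal only)
 */
#include <R.h>
#include <math.h>

#define N_PARMS 29

static double parms[N_PARMS];

void rab_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

static double eval_component(const double *blk, double R5, double R7)
{
    int kind = (int) blk[0];
    int reg  = (int) blk[1];
    double x = (reg == 1) ? R5 : (reg == 2) ? R7 : 0.0;
    double V, Km, h, xh;

    switch (kind) {
    case 0: /* absent */
        return 0.0;
    case 1: /* intrinsic */
        return blk[2];
    case 2: /* Michaelis-Menten */
        V = blk[2]; Km = blk[3];
        return V * x / (Km + x);
    case 3: /* sigmoidal (Hill) */
        V = blk[2]; Km = blk[3]; h = blk[4];
        xh = pow(x, h);
        return V * xh / (pow(Km, h) + xh);
    case 4: /* exchange inhibition */
        V = blk[2]; Km = blk[3];
        return V * Km / (Km + x);
    case 5: /* linear */
        return blk[2] * x;
    default:
        return 0.0;
    }
}

void rab_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double r5 = y[0], R5 = y[1], r7 = y[2], R7 = y[3];
    double K1 = parms[0], k1 = parms[1], K2 = parms[2], k2 = parms[3];

    double gef5 = eval_component(parms + 4,      R5, R7);
    double gap5 = eval_component(parms + 4 + 5,  R5, R7);
    double gef7 = eval_component(parms + 4 + 10, R5, R7)
                + eval_component(parms + 4 + 15, R5, R7);
    double gap7 = eval_component(parms + 4 + 20, R5, R7);

    ydot[0] = K1 - (k1 + gef5) * r5 + gap5 * R5;
    ydot[1] = gef5 * r5 - gap5 * R5;
    ydot[2] = K2 - (k2 + gef7) * r7 + gap7 * R7;
    ydot[3] = gef7 * r7 - gap7 * R7;
}
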